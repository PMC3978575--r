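# Small programmatic fixtures.

# A 64x64 image whose "breast" is a centred rectangle filled with the given
# values (recycled); background at `background`. Returns image + mask.
rect_breast <- function(values, background = 0L, bit_depth = 8L,
                        nr = 64L, nc = 64L, source_id = "fixture") {
  px <- matrix(as.integer(background), nr, nc)
  rows <- 17:48; cols <- 17:48
  mask <- matrix(FALSE, nr, nc)
  mask[rows, cols] <- TRUE
  px[mask] <- as.integer(values)
  list(image = grey_image(px, bit_depth, source_id),
       mask = breast_mask(mask, chest_edge = "left", check = FALSE))
}

# Minimal valid cohort records built from explicit outcome/group vectors;
# all covariates at reference unless overridden.
toy_records <- function(outcome, density_group,
                        age_group = "40-49", ht_use = "no",
                        family_history = "no", symptoms = "none",
                        screening_round = "first", weight = 1,
                        dense_area = seq_along(outcome)) {
  n <- length(outcome)
  data.frame(
    woman_id = sprintf("T%05d", seq_len(n)),
    age_group = rep_len(age_group, n),
    ht_use = rep_len(ht_use, n),
    family_history = rep_len(family_history, n),
    symptoms = rep_len(symptoms, n),
    screening_round = rep_len(screening_round, n),
    outcome = outcome,
    tumour_size_mm = ifelse(outcome == "control", NA_real_, 10),
    dense_area_px_a = rep_len(dense_area, n),
    dense_area_px_b = rep_len(dense_area, n),
    weight = rep_len(weight, n),
    density_group = rep_len(density_group, n),
    stringsAsFactors = FALSE
  )
}
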