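# Minimal assessment-record table for metric tests.
make_records <- function(detected, ccs = NULL, usable = NULL,
                         patient = "P1", group = "feedback") {
  n <- length(detected)
  tibble::tibble(
    patient_id = rep_len(patient, n), group = rep_len(group, n),
    assessment_index = seq_len(n),
    timestamp = sprintf("2019-06-%02dT09:00:00", 1 + (seq_len(n) - 1) %% 28),
    image_path = NA_character_, checker_detected = detected,
    usable_label = if (is.null(usable)) rep(NA, n) else usable,
    ccs = if (is.null(ccs)) rep(NA_real_, n) else ccs,
    duration_s = rep(40, n))
}
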