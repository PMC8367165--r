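# Independent oracles, deliberately written in the most naive way possible
# so they share no code with the implementation under test.

# Double-loop 3x3 Laplacian convolution with edge-clamped indexing.
naive_laplacian <- function(g) {
  h <- nrow(g); w <- ncol(g)
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    acc <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), h)
      jj <- min(max(j + dj, 1), w)
      acc <- acc + k[di + 2, dj + 2] * g[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Exact two-sided permutation p-value of the rank-sum statistic: enumerate
# every assignment of pooled ranks to sample A and count statistics at
# least as extreme as observed.
perm_ranksum_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  e <- length(a) * (n + 1) / 2
  sel <- utils::combn(n, length(a))
  ws <- colSums(matrix(r[sel], nrow = length(a)))
  mean(abs(ws - e) >= abs(w_obs - e) - 1e-9)
}

# Naive per-patient summary by split + base arithmetic.
naive_patient_summary <- function(records) {
  parts <- split(records, records$patient_id)
  do.call(rbind, lapply(parts, function(s) {
    ccs <- s$ccs[!is.na(s$ccs)]
    data.frame(patient_id = s$patient_id[1],
               ccdr = sum(s$checker_detected) / nrow(s),
               ccs_median = if (length(ccs)) unname(quantile(ccs, 0.5)) else NA)
  }))
}

# A quick renderable fixture: sharp default scene plus its ground truth.
fixture_scene <- function(...) render_scene(scene_spec(...))
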