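# Independent brute-force oracles used to cross-check the implementation.

# hypergeometric upper tail by combinatorial sum (independent of phyper)
oracle_hyper_upper <- function(N, n, C, O) {
  ks <- seq(O, min(n, C))
  if (length(ks) == 0 || O > min(n, C)) return(0)
  sum(choose(C, ks) * choose(N - C, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg by the literal step-up recipe
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in seq(m - 1, 1, length.out = max(m - 1, 0))) {
    adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# consistent-direction call by a per-row sign scan
oracle_direction <- function(delta_matrix) {
  apply(delta_matrix, 1, function(d) {
    if (all(d > 0)) "up" else if (all(d < 0)) "down" else "none"
  })
}

# CpG O/E and GC by a literal character scan
oracle_oe <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  keep <- s != "N"
  n_c <- sum(s == "C"); n_g <- sum(s == "G")
  n_cg <- 0
  for (i in seq_len(length(s) - 1)) {
    if (s[i] == "C" && s[i + 1] == "G") n_cg <- n_cg + 1
  }
  if (n_c == 0 || n_g == 0) return(0)
  n_cg * sum(keep) / (n_c * n_g)
}

# tiny bundle built straight from a delta specification: normal columns all
# zero, tumor columns equal to the per-pair deltas (already log2-centered
# scale markers for direction logic)
delta_bundle <- function(delta_matrix, feature_type = "gene") {
  n_pat <- ncol(delta_matrix)
  ids <- rownames(delta_matrix) %||% sprintf("F%04d", seq_len(nrow(delta_matrix)))
  patients <- sprintf("P%02d", seq_len(n_pat))
  v <- cbind(delta_matrix, matrix(0, nrow(delta_matrix), n_pat))
  dimnames(v) <- list(ids, c(paste0(patients, "_T"), paste0(patients, "_N")))
  expression_bundle(
    v, matrix(TRUE, nrow(v), ncol(v), dimnames = dimnames(v)),
    tibble::tibble(
      sample_id = colnames(v),
      patient_id = rep(patients, 2),
      tissue = rep(c("tumor", "normal"), each = n_pat)
    ),
    scale = "log2_centered", feature_type = feature_type
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
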