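# Independent reference implementations used as oracles.

# brute-force restriction-site scan: compare every rotation's substring
brute_digest_cuts <- function(seq, site, cut_offset = 1L, circular = TRUE) {
  L <- nchar(seq)
  k <- nchar(site)
  ext <- if (circular) paste0(seq, seq) else seq
  starts <- integer()
  last <- if (circular) L - 1L else L - k
  for (s in 0:last) {
    if (s < 0) next
    if (substr(ext, s + 1L, s + k) == site) starts <- c(starts, s)
  }
  cuts <- starts + cut_offset
  if (circular) sort(unique(cuts %% L)) else
    sort(unique(cuts[cuts > 0 & cuts < L]))
}

# linear interval search over the fragment table (wrap-aware)
linear_assign <- function(fragmap, pos) {
  fr <- fragmap$fragments
  L <- fragmap$genome$length
  vapply(pos, function(p) {
    for (r in seq_len(nrow(fr))) {
      if (fr$wraps[r]) {
        if (p >= fr$start[r] || p < fr$end[r]) return(r)
      } else {
        if (p >= fr$start[r] && p < fr$end[r]) return(r)
      }
    }
    stop("position not covered: ", p)
  }, integer(1))
}

# naive alternating L1 balancing, written as plain loops
scn_reference <- function(M, tol = 1e-6, max_iter = 200) {
  for (it in 1:max_iter) {
    for (r in seq_len(nrow(M))) M[r, ] <- M[r, ] / sum(M[r, ])
    for (c in seq_len(ncol(M))) M[, c] <- M[, c] / sum(M[, c])
    resid <- 0
    for (r in seq_len(nrow(M))) resid <- max(resid, abs(sum(M[r, ]) - 1))
    if (resid < tol) break
  }
  (M + t(M)) / 2
}

# random A/C/G/T string
random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")
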