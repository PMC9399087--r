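# Independent oracles used to cross-check the package implementation.
# These deliberately share no code with the package internals: the index
# oracle is a plain loop over clones, and the kinetics oracle is the exact
# matrix-exponential solution of the linear two-state system.

# Brute-force cysteine index: re-scan every clone, recount, apply the
# detection-count filter, the Trbv1 short-CDR3 rule and the zero-Cys
# reciprocal fallback by hand.
oracle_cys_index <- function(clones, min_count = 3, trbv1_min_len = 8) {
  n_elig <- 0L
  n_cys <- 0L
  for (i in seq_len(nrow(clones))) {
    if (clones$detection_count[i] < min_count) next
    aa <- clones$cdr3_aa[i]
    len <- nchar(aa)
    if (!is.na(clones$chain[i]) && clones$chain[i] == "beta" &&
        clones$v_gene[i] == "TRBV1" && len < trbv1_min_len) next
    n_elig <- n_elig + 1L
    apex <- floor(len / 2) + 1
    hit <- FALSE
    for (p in seq_len(len)) {
      if (substr(aa, p, p) == "C" && abs(p - apex) <= 2) hit <- TRUE
    }
    if (hit) n_cys <- n_cys + 1L
  }
  if (n_elig == 0L) return(NULL)
  list(
    n_eligible = n_elig, n_apex_cys = n_cys,
    index_percent = if (n_cys == 0L) 100 / n_elig else 100 * n_cys / n_elig
  )
}

# Random clone tables built directly with base R (independent of the
# package's generator) for oracle-equivalence fixtures.
random_clone_table <- function(n_clones, p_cys = 0.15, p_trbv1 = 0.2,
                               p_low_count = 0.3) {
  aa_pool <- c("A", "S", "G", "N", "T", "L", "Y", "R", "Q", "E")
  genes <- c("TRBV1", "TRBV2", "TRBV13-2", "TRBV19")
  rows <- lapply(seq_len(n_clones), function(i) {
    len <- sample(4:16, 1)
    aa <- sample(aa_pool, len, replace = TRUE)
    if (runif(1) < p_cys) aa[sample(len, 1)] <- "C"
    cdr3 <- paste(aa, collapse = "")
    junction <- paste0("C", cdr3, "F")
    v <- if (runif(1) < p_trbv1) "TRBV1" else sample(genes[-1], 1)
    cnt <- if (runif(1) < p_low_count) sample(1:2, 1) else sample(3:30, 1)
    data.frame(v_gene = v, chain = "beta",
               junction_aa = junction, cdr3_aa = cdr3,
               detection_count = cnt, productive = TRUE,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  # unique nucleotide keys so the sample constructor accepts the table
  tab$cdr3_nt <- sprintf("NT%06d", seq_len(n_clones))
  tab
}

clone_table_as_sample <- function(tab, sample_id = "fixture") {
  repertoire_sample(tab, sample_id = sample_id, chain = "beta")
}

# Exact solution of the piecewise-linear two-state system via the augmented
# (affine) matrix exponential: d/dt [Bnc, Bcov, 1] = M [Bnc, Bcov, 1].
oracle_two_state <- function(params, schedule, times) {
  segs <- schedule$segments
  t_start <- c(0, head(segs$t_end, -1))
  state <- c(0, 0)
  out <- matrix(NA_real_, nrow = length(times), ncol = 2,
                dimnames = list(NULL, c("Bnc", "Bcov")))
  for (i in seq_len(nrow(segs))) {
    C <- segs$concentration[i]
    M <- rbind(
      c(-params$kon * C - params$koff - params$kcov, -params$kon * C,
        params$kon * C * params$rmax),
      c(params$kcov, 0, 0),
      c(0, 0, 0)
    )
    in_seg <- which(times >= t_start[i] - 1e-12 &
                      times <= segs$t_end[i] + 1e-12)
    for (j in in_seg) {
      dtau <- times[j] - t_start[i]
      v <- as.numeric(Matrix::expm(M * dtau) %*% c(state, 1))
      out[j, ] <- v[1:2]
    }
    v_end <- as.numeric(Matrix::expm(M * segs$duration[i]) %*% c(state, 1))
    state <- v_end[1:2]
  }
  out
}
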