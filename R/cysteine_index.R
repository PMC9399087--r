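#' Middle (apex) position of a CDR3
#'
#' For a CDR3 of `n` amino acids the apex is the residue at the largest
#' position not greater than `n/2 + 1`, i.e. `floor(n/2) + 1` (1-based,
#' CDR3-IMGT coordinates).
#'
#' @param n Integer vector of CDR3 lengths (>= 1).
#' @return Integer vector of apex positions.
#' @examples
#' middle_position(c(1, 10, 11)) # 1, 6, 6
#' @export
middle_position <- function(n) {
  n <- as.integer(n)
  if (any(is.na(n)) || any(n < 1L)) {
    stop("CDR3 length must be a positive integer", call. = FALSE)
  }
  n %/% 2L + 1L
}

#' Does a CDR3 carry a cysteine near its apex?
#'
#' TRUE when any Cys sits within two positions of the apex (a five-residue
#' window, clipped at the CDR3 boundaries).
#'
#' @param cdr3_aa Character vector of CDR3-IMGT amino-acid sequences
#'   (non-empty). Non-standard residues such as `X` never count as Cys.
#' @param window Half-width of the apex window (default 2).
#' @return Logical vector.
#' @examples
#' has_apex_cysteine(c("ASSGGCNTLY", "ASCGGGNTLY")) # TRUE, FALSE
#' @export
has_apex_cysteine <- function(cdr3_aa, window = 2L) {
  if (any(!nzchar(cdr3_aa))) {
    stop("cdr3_aa must be non-empty", call. = FALSE)
  }
  apex <- middle_position(nchar(cdr3_aa))
  vapply(seq_along(cdr3_aa), function(i) {
    pos <- which(strsplit(cdr3_aa[[i]], "", fixed = TRUE)[[1]] == "C")
    any(abs(pos - apex[[i]]) <= window)
  }, logical(1))
}

#' Clones eligible for the cysteine index
#'
#' Applies the two exclusion rules of the index: clones detected only once or
#' twice in the sample are excluded, and beta-chain Trbv1 clones with a CDR3
#' shorter than 8 amino acids are excluded (Trbv1 can carry a germline-encoded
#' Cys at CDR3 position 2, which falls inside the apex window only for CDR3s
#' of fewer than 8 residues). Exclusion tallies are attached as attributes
#' `n_excluded_low_count` and `n_excluded_trbv1`.
#'
#' @param sample A productivity-filtered `repertoire_sample`.
#' @param min_count Minimum detection count (default 3).
#' @param trbv1_min_len Minimum CDR3-IMGT length for Trbv1 beta clones
#'   (default 8).
#' @return The eligible subset as a `repertoire_sample` with tally attributes.
#' @export
eligible_clones <- function(sample, min_count = 3L, trbv1_min_len = 8L) {
  low <- sample$detection_count < min_count
  trbv1_short <- !low &
    !is.na(sample$chain) & sample$chain == "beta" &
    sample$v_gene == "TRBV1" &
    nchar(sample$cdr3_aa) < trbv1_min_len
  out <- .restamp(sample[!(low | trbv1_short), , drop = FALSE], sample)
  attr(out, "n_excluded_low_count") <- sum(low)
  attr(out, "n_excluded_trbv1") <- sum(trbv1_short)
  out
}

#' Cysteine index of a repertoire sample
#'
#' The cysteine index is the percentage of eligible clones (see
#' [eligible_clones()]) whose CDR3 carries a Cys within two positions of the
#' apex. Each clone counts once, regardless of its detection count. If no
#' eligible clone has an apex Cys, the index falls back to the reciprocal of
#' the eligible-clone count expressed as a percentage, so the index is always
#' strictly positive.
#'
#' @inheritParams eligible_clones
#' @return A `cys_index_result` list: `sample_id`, `chain`, `n_eligible`,
#'   `n_apex_cys`, `index_percent`, `zero_fallback_used`,
#'   `n_excluded_low_count`, `n_excluded_trbv1`.
#' @export
cysteine_index <- function(sample, min_count = 3L, trbv1_min_len = 8L) {
  elig <- eligible_clones(sample, min_count = min_count,
                          trbv1_min_len = trbv1_min_len)
  n <- nrow(elig)
  if (n == 0L) {
    stop("empty sample: no clones remain after eligibility filters",
         call. = FALSE)
  }
  n_cys <- sum(has_apex_cysteine(elig$cdr3_aa))
  fallback <- n_cys == 0L
  meta <- sample_meta(sample)
  structure(
    list(
      sample_id = meta$sample_id,
      chain = meta$chain,
      n_eligible = n,
      n_apex_cys = n_cys,
      index_percent = if (fallback) 100 / n else 100 * n_cys / n,
      zero_fallback_used = fallback,
      n_excluded_low_count = attr(elig, "n_excluded_low_count"),
      n_excluded_trbv1 = attr(elig, "n_excluded_trbv1")
    ),
    class = "cys_index_result"
  )
}

#' @export
print.cys_index_result <- function(x, ...) {
  cat(sprintf(
    "<cys_index_result> %s (%s): %.3f%% (%d/%d apex-Cys%s; excluded %d low-count, %d Trbv1-short)\n",
    x$sample_id, x$chain, x$index_percent, x$n_apex_cys, x$n_eligible,
    if (x$zero_fallback_used) "; zero fallback" else "",
    x$n_excluded_low_count, x$n_excluded_trbv1))
  invisible(x)
}

#' Cysteine indices for many samples as a tidy table
#'
#' @param samples List of `repertoire_sample` objects.
#' @inheritParams eligible_clones
#' @return Tibble with one row per sample: metadata columns plus the
#'   `cys_index_result` fields.
#' @export
cysteine_index_table <- function(samples, min_count = 3L,
                                 trbv1_min_len = 8L) {
  purrr::map_dfr(samples, function(s) {
    r <- cysteine_index(s, min_count = min_count,
                        trbv1_min_len = trbv1_min_len)
    meta <- sample_meta(s)
    tibble(
      sample_id = r$sample_id, chain = r$chain,
      lineage = meta$lineage, genotype = meta$genotype,
      n_eligible = r$n_eligible, n_apex_cys = r$n_apex_cys,
      index_percent = r$index_percent,
      zero_fallback_used = r$zero_fallback_used,
      n_excluded_low_count = r$n_excluded_low_count,
      n_excluded_trbv1 = r$n_excluded_trbv1
    )
  })
}
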