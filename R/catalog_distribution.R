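#' Build a lineage reference catalog
#'
#' Aggregates all clones detected across the samples of one T cell lineage
#' into a reference catalog. Clones from different samples stay distinct
#' entries even when identical in sequence (no cross-sample deduplication),
#' so a clonotype detected in two mice contributes two clones. Neither the
#' detection-count filter nor the Trbv1 rule applies to catalogs.
#'
#' @param samples List of `repertoire_sample` objects, all with the stated
#'   lineage.
#' @param lineage_label Lineage of the catalog (e.g. `"CD4_Tconv"`).
#' @return A `reference_catalog` tibble (clone rows plus `sample_id`), with
#'   attributes `lineage_label` and `total_clones`.
#' @export
build_catalog <- function(samples, lineage_label) {
  if (length(samples) == 0) {
    stop("cannot build a catalog from an empty sample list", call. = FALSE)
  }
  lin <- vapply(samples, function(s) attr(s, "lineage"), character(1))
  if (any(lin != lineage_label)) {
    stop("labeling error: sample lineage(s) ",
         paste(unique(lin[lin != lineage_label]), collapse = ", "),
         " do not match catalog lineage ", lineage_label, call. = FALSE)
  }
  clones <- purrr::map_dfr(samples, function(s) {
    dplyr::mutate(as_tibble(s), sample_id = attr(s, "sample_id"))
  })
  structure(clones,
            lineage_label = lineage_label,
            total_clones = nrow(clones),
            class = c("reference_catalog", class(clones)))
}

#' Clonotype distribution across reference catalogs
#'
#' A clonotype is a unique `(v_gene, cdr3_aa)` pair. Its intra-lineage
#' frequency in a catalog is the number of clones encoding the clonotype
#' divided by the catalog's total clone count; its distribution is the
#' intra-lineage frequencies normalized to sum to 100 percent across the
#' four catalogs.
#'
#' @param clonotype List or one-row data frame with `v_gene` and `cdr3_aa`
#'   (gene names are normalized before matching).
#' @param catalogs List of exactly 4 `reference_catalog` objects.
#' @return A `catalog_distribution` list: `clonotype`, `lineages`,
#'   `intra_lineage_freq`, `distribution_percent` (both named by lineage).
#' @export
distribution_across_catalogs <- function(clonotype, catalogs) {
  if (length(catalogs) != 4) {
    stop("exactly 4 reference catalogs are required", call. = FALSE)
  }
  v <- normalize_v_gene(clonotype$v_gene)
  aa <- as.character(clonotype$cdr3_aa)
  lineages <- vapply(catalogs, function(k) attr(k, "lineage_label"),
                     character(1))
  freq <- vapply(catalogs, function(k) {
    sum(k$v_gene == v & k$cdr3_aa == aa) / attr(k, "total_clones")
  }, numeric(1))
  names(freq) <- lineages
  if (sum(freq) == 0) {
    stop("clonotype ", v, "/", aa, " not found in any catalog",
         call. = FALSE)
  }
  structure(
    list(
      clonotype = list(v_gene = v, cdr3_aa = aa),
      lineages = lineages,
      intra_lineage_freq = freq,
      distribution_percent = 100 * freq / sum(freq)
    ),
    class = "catalog_distribution"
  )
}

#' @export
print.catalog_distribution <- function(x, ...) {
  cat(sprintf("<catalog_distribution> %s / %s\n",
              x$clonotype$v_gene, x$clonotype$cdr3_aa))
  print(round(x$distribution_percent, 3))
  invisible(x)
}

#' Distribution table for many clonotypes
#'
#' @param clonotypes Data frame with columns `v_gene`, `cdr3_aa`.
#' @param catalogs List of exactly 4 `reference_catalog` objects.
#' @return Tibble with one row per clonotype and one percentage column per
#'   lineage (`pct_<lineage>`); clonotypes absent from every catalog get NA.
#' @export
catalog_distribution_table <- function(clonotypes, catalogs) {
  lineages <- vapply(catalogs, function(k) attr(k, "lineage_label"),
                     character(1))
  purrr::pmap_dfr(
    clonotypes[, c("v_gene", "cdr3_aa")],
    function(v_gene, cdr3_aa) {
      ct <- list(v_gene = v_gene, cdr3_aa = cdr3_aa)
      pct <- tryCatch(
        distribution_across_catalogs(ct, catalogs)$distribution_percent,
        error = function(e) setNames(rep(NA_real_, 4), lineages)
      )
      dplyr::bind_cols(
        tibble(v_gene = normalize_v_gene(v_gene), cdr3_aa = cdr3_aa),
        as_tibble(as.list(setNames(pct, paste0("pct_", names(pct)))))
      )
    }
  )
}
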