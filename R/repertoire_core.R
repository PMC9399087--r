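#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Columns every clone table carries. A "clone" is a unique combination of a V
# gene and a CDR3 nucleotide sequence within one sample; repertoire statistics
# count each clone once regardless of detection_count.
.clone_cols <- c(
  "v_gene", "chain", "cdr3_nt", "junction_aa", "cdr3_aa",
  "detection_count", "productive"
)

#' Normalize a V gene call to a bare gene symbol
#'
#' Strips IMGT allele suffixes (`*01`), any leading `"mouse "` species prefix
#' and surrounding whitespace, and upper-cases the symbol, so that
#' `"mouse Trbv1*02"` and `"TRBV1"` key the same clone. Clones are keyed on
#' the gene, not the allele.
#'
#' @param v_call Character vector of V gene calls.
#' @return Character vector of normalized gene symbols.
#' @examples
#' normalize_v_gene(c("Trbv1*01", "mouse TRAV14*02 "))
#' @export
normalize_v_gene <- function(v_call) {
  v <- trimws(as.character(v_call))
  v <- sub("^mouse\\s+", "", v, ignore.case = TRUE)
  v <- sub("\\*.*$", "", v)
  # a v_call may list several comma-separated hits; the first is the call
  v <- sub(",.*$", "", v)
  toupper(trimws(v))
}

#' Infer receptor chain from a V gene symbol
#'
#' @param v_gene Character vector of (normalized) V gene symbols.
#' @return Character vector, `"alpha"` or `"beta"` (`NA` if unrecognized).
#' @export
infer_chain <- function(v_gene) {
  g <- toupper(v_gene)
  dplyr::case_when(
    startsWith(g, "TRAV") ~ "alpha",
    startsWith(g, "TRBV") ~ "beta",
    TRUE ~ NA_character_
  )
}

#' Extract the CDR3-IMGT amino-acid sequence from a junction
#'
#' The junction includes the conserved N-terminal Cys and C-terminal Trp/Phe;
#' CDR3-IMGT removes both flanking residues, so the output is always two
#' residues shorter than the input.
#'
#' @param junction_aa Character vector of junction amino-acid sequences
#'   (length >= 3 each).
#' @return Character vector of CDR3-IMGT sequences.
#' @examples
#' extract_cdr3_imgt("CASSLGQNTLYF") # "ASSLGQNTLY"
#' @export
extract_cdr3_imgt <- function(junction_aa) {
  n <- nchar(junction_aa)
  if (any(n < 3, na.rm = TRUE)) {
    stop("degenerate junction: junction_aa must be at least 3 residues long",
         call. = FALSE)
  }
  substr(junction_aa, 2L, n - 1L)
}

#' Assemble a repertoire sample from a clone table
#'
#' A `repertoire_sample` is a tibble of clones (one row per unique
#' `(v_gene, cdr3_nt)` pair) with sample metadata attached as attributes.
#'
#' @param clones Data frame with columns `v_gene`, `cdr3_nt`, `junction_aa`,
#'   `detection_count`; `chain`, `cdr3_aa` and `productive` are derived when
#'   absent.
#' @param sample_id Sample identifier.
#' @param chain `"alpha"`, `"beta"` or `"mixed"`; inferred from the clones
#'   when `NULL`.
#' @param lineage T cell lineage label (e.g. `"preselection"`, `"CD4_Tconv"`,
#'   `"CD8_Tconv"`, `"Treg"`, `"CD8aaIEL"`, `"other"`).
#' @param genotype Genotype label (e.g. `"wild_type"`).
#' @return A `repertoire_sample` tibble.
#' @export
repertoire_sample <- function(clones, sample_id = "sample",
                              chain = NULL, lineage = "other",
                              genotype = "wild_type") {
  clones <- as_tibble(clones)
  stopifnot(all(c("v_gene", "cdr3_nt", "junction_aa", "detection_count")
                %in% names(clones)))
  if (!"chain" %in% names(clones)) clones$chain <- infer_chain(clones$v_gene)
  if (!"cdr3_aa" %in% names(clones)) {
    clones$cdr3_aa <- extract_cdr3_imgt(clones$junction_aa)
  }
  if (!"productive" %in% names(clones)) {
    clones$productive <- is_productive_junction(clones$cdr3_nt,
                                                clones$junction_aa)
  }
  if (anyDuplicated(clones[, c("v_gene", "cdr3_nt")])) {
    stop("clone table has duplicate (v_gene, cdr3_nt) pairs; ",
         "merge rows before constructing a sample", call. = FALSE)
  }
  if (any(clones$detection_count < 1)) {
    stop("detection_count must be >= 1", call. = FALSE)
  }
  if (is.null(chain)) {
    ch <- unique(clones$chain[!is.na(clones$chain)])
    chain <- if (length(ch) == 1) ch else "mixed"
  }
  structure(
    clones[, union(.clone_cols, names(clones))],
    sample_id = sample_id, chain = chain, lineage = lineage,
    genotype = genotype,
    class = c("repertoire_sample", class(clones))
  )
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf("<repertoire_sample> %s | chain: %s | lineage: %s | genotype: %s\n",
              attr(x, "sample_id"), attr(x, "chain"), attr(x, "lineage"),
              attr(x, "genotype")))
  cat(sprintf("  %d clones, %d productive\n", nrow(x), sum(x$productive)))
  NextMethod()
}

#' Sample metadata accessor
#'
#' @param sample A `repertoire_sample`.
#' @return Named list with `sample_id`, `chain`, `lineage`, `genotype`.
#' @export
sample_meta <- function(sample) {
  list(sample_id = attr(sample, "sample_id"),
       chain = attr(sample, "chain"),
       lineage = attr(sample, "lineage"),
       genotype = attr(sample, "genotype"))
}

# keep sample attributes through dplyr-style subsetting used internally
.restamp <- function(clones, sample) {
  meta <- sample_meta(sample)
  repertoire_sample(as_tibble(clones), sample_id = meta$sample_id,
                    chain = meta$chain, lineage = meta$lineage,
                    genotype = meta$genotype)
}

.stop_codon <- "*"

#' Productivity of a junction
#'
#' A junction is productive when its nucleotide length is a multiple of three
#' and its amino-acid sequence contains no stop symbol (`*`).
#'
#' @param cdr3_nt Nucleotide junction sequences.
#' @param junction_aa Amino-acid junction sequences.
#' @return Logical vector.
#' @export
is_productive_junction <- function(cdr3_nt, junction_aa) {
  (nchar(cdr3_nt) %% 3L == 0L) &
    !grepl(.stop_codon, junction_aa, fixed = TRUE)
}

#' Remove out-of-frame and stop-codon clones
#'
#' Drops clones whose junction nucleotide length is not a multiple of three or
#' whose junction amino-acid sequence contains a stop codon.
#'
#' @param sample A `repertoire_sample`.
#' @return The filtered `repertoire_sample`.
#' @export
filter_productive <- function(sample) {
  keep <- is_productive_junction(sample$cdr3_nt, sample$junction_aa)
  .restamp(sample[keep, , drop = FALSE], sample)
}

.airr_required <- c("v_call", "junction", "junction_aa", "duplicate_count")

#' Read an AIRR Rearrangement clone table
#'
#' Reads a tab-separated AIRR Rearrangement file, drops rows lacking a
#' junction (logged via a message), and deduplicates rows into clones keyed by
#' normalized `(v_gene, cdr3_nt)` with `detection_count` equal to the sum of
#' `duplicate_count` over the merged rows.
#'
#' @param path Path to an AIRR TSV with at least columns `v_call`, `junction`,
#'   `junction_aa`, `duplicate_count`.
#' @param sample_id,lineage,genotype Sample metadata; default to values read
#'   from a `<path>.meta` sidecar of `key: value` lines when present.
#' @return A `repertoire_sample`.
#' @export
parse_airr <- function(path, sample_id = NULL, lineage = NULL,
                       genotype = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    stop("empty sample: ", path, " contains no rearrangement rows",
         call. = FALSE)
  }
  missing_cols <- setdiff(.airr_required, names(raw))
  if (length(missing_cols)) {
    stop("AIRR format error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  meta <- .read_meta_sidecar(paste0(path, ".meta"))
  sample_id <- sample_id %||% meta$sample_id %||%
    sub("\\.(airr\\.)?tsv$", "", basename(path))
  lineage <- lineage %||% meta$lineage %||% "other"
  genotype <- genotype %||% meta$genotype %||% "wild_type"

  no_junction <- is.na(raw$junction) | raw$junction == "" |
    is.na(raw$junction_aa) | raw$junction_aa == ""
  if (any(no_junction)) {
    message(sum(no_junction), " row(s) without a junction dropped from ",
            basename(path))
    raw <- raw[!no_junction, , drop = FALSE]
  }
  if (nrow(raw) == 0) {
    stop("empty sample: no rows with a junction in ", path, call. = FALSE)
  }

  clones <- raw |>
    dplyr::mutate(
      v_gene = normalize_v_gene(.data$v_call),
      cdr3_nt = toupper(.data$junction),
      detection_count = as.integer(.data$duplicate_count)
    ) |>
    dplyr::group_by(.data$v_gene, .data$cdr3_nt) |>
    dplyr::summarise(
      junction_aa = dplyr::first(.data$junction_aa),
      detection_count = sum(.data$detection_count),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$v_gene, .data$cdr3_nt)

  repertoire_sample(clones, sample_id = sample_id,
                    chain = meta$chain, lineage = lineage,
                    genotype = genotype)
}

.read_meta_sidecar <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  setNames(
    lapply(kv, function(x) trimws(paste(x[-1], collapse = ":"))),
    vapply(kv, function(x) trimws(x[[1]]), character(1))
  )
}

#' Write a repertoire sample as an AIRR Rearrangement TSV
#'
#' Emits one row per clone with columns `v_call`, `junction`, `junction_aa`,
#' `duplicate_count` and `productive`, plus a `<path>.meta` metadata sidecar.
#' `parse_airr(write_airr(s))` reproduces the clone set of `s`.
#'
#' @param sample A `repertoire_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(sample, path) {
  out <- tibble(
    v_call = sample$v_gene,
    junction = sample$cdr3_nt,
    junction_aa = sample$junction_aa,
    duplicate_count = sample$detection_count,
    productive = ifelse(sample$productive, "T", "F")
  )
  readr::write_tsv(out, path, progress = FALSE)
  meta <- sample_meta(sample)
  writeLines(
    sprintf("%s: %s", names(meta), unlist(meta)),
    paste0(path, ".meta")
  )
  invisible(path)
}
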