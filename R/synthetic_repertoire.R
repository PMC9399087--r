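# Seeded generator of AIRR-style clone tables with the statistical structure
# the repertoire analysis assumes: per-lineage apex-cysteine enrichment, a
# Trbv1 germline Cys at CDR3 position 2, heavy-tailed detection counts with
# configurable singleton/doubleton mass, and codon back-translation so that
# distinct nucleotide clones can encode one amino-acid clonotype.

.aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# standard codon table, amino acid -> codons (back-translation only)
.codons <- list(
  A = c("GCT", "GCC", "GCA", "GCG"),
  R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  K = c("AAA", "AAG"), M = "ATG", F = c("TTT", "TTC"),
  P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG",
  Y = c("TAT", "TAC"), V = c("GTT", "GTC", "GTA", "GTG")
)

.default_lengths <- function() {
  len <- 4:20
  w <- stats::dnorm(len, mean = 11, sd = 2.2)
  setNames(w / sum(w), len)
}

.default_v_usage <- function(chain) {
  genes <- if (chain == "beta") {
    c("TRBV1", "TRBV2", "TRBV4", "TRBV5", "TRBV12-1", "TRBV13-2",
      "TRBV16", "TRBV19", "TRBV29", "TRBV31")
  } else {
    c("TRAV3-3", "TRAV4-3", "TRAV6-5", "TRAV7-2", "TRAV9-4", "TRAV12-1",
      "TRAV13-1", "TRAV14-1", "TRAV16", "TRAV21")
  }
  setNames(rep(1 / length(genes), length(genes)), genes)
}

#' Background amino-acid frequencies for CDR3 generation
#'
#' Uniform over the 20 standard residues with cysteine down-weighted (1
#' percent by default), so apex-window Cys content is driven almost entirely
#' by the engineered `apex_cys_prob` rather than background leakage. Set
#' `cys_freq = 0` for leakage-free parameter-recovery experiments.
#'
#' @param cys_freq Background cysteine frequency.
#' @return Named probability vector over the 20 amino acids.
#' @export
residue_frequencies <- function(cys_freq = 0.01) {
  p <- rep((1 - cys_freq) / 19, 20)
  names(p) <- .aa20
  p["C"] <- cys_freq
  p / sum(p)
}
.default_residue_freq <- residue_frequencies

#' Lineage profile for the synthetic repertoire generator
#'
#' Describes one T cell lineage's clone-generating law: number of clones,
#' probability of an engineered apex-window cysteine, CDR3 length and V gene
#' usage distributions, background residue frequencies, and the detection
#' count law (with explicit singleton/doubleton mass so the detection-count
#' filter is exercised).
#'
#' @param lineage Lineage label.
#' @param n_clones Clones to draw per sample.
#' @param apex_cys_prob Probability that a clone is forced to carry a Cys in
#'   the apex window (placed uniformly within the clipped window).
#' @param chain `"alpha"` or `"beta"`.
#' @param cdr3_length_distribution Named probability vector over CDR3-IMGT
#'   lengths 4-20 (names are lengths).
#' @param v_gene_usage Named probability vector over a V gene panel.
#' @param trbv1_germline_cys Force a Cys at CDR3 position 2 of Trbv1 clones
#'   (the germline-encoded Cys the Trbv1 exclusion rule exists for).
#' @param residue_freq Named background amino-acid frequencies (20 residues).
#' @param singleton_fraction Fraction of clones drawn with detection count 1
#'   or 2 (excluded from the cysteine index); remaining mass sits on counts
#'   >= 3 with a geometric tail.
#' @param count_geom_prob Geometric tail parameter of the count law.
#' @return A `lineage_profile` list.
#' @export
lineage_profile <- function(lineage = "other",
                            n_clones = 5000L,
                            apex_cys_prob = 0.03,
                            chain = "beta",
                            cdr3_length_distribution = .default_lengths(),
                            v_gene_usage = .default_v_usage(chain),
                            trbv1_germline_cys = TRUE,
                            residue_freq = .default_residue_freq(),
                            singleton_fraction = 0.2,
                            count_geom_prob = 0.3) {
  stopifnot(n_clones >= 1,
            apex_cys_prob >= 0, apex_cys_prob <= 1,
            singleton_fraction >= 0, singleton_fraction <= 1,
            chain %in% c("alpha", "beta"))
  for (p in list(cdr3_length_distribution, v_gene_usage, residue_freq)) {
    if (abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
      stop("probability vectors must be nonnegative and sum to 1",
           call. = FALSE)
    }
  }
  if (apex_cys_prob > 0 &&
      all(as.integer(names(cdr3_length_distribution)
                     [cdr3_length_distribution > 0]) < 1)) {
    stop("config error: apex-window Cys impossible with zero-length CDR3s",
         call. = FALSE)
  }
  structure(
    list(lineage = lineage, n_clones = as.integer(n_clones),
         apex_cys_prob = apex_cys_prob, chain = chain,
         cdr3_length_distribution = cdr3_length_distribution,
         v_gene_usage = v_gene_usage,
         trbv1_germline_cys = trbv1_germline_cys,
         residue_freq = residue_freq,
         singleton_fraction = singleton_fraction,
         count_geom_prob = count_geom_prob),
    class = "lineage_profile"
  )
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.back_translate <- function(aa_seq) {
  vapply(strsplit(aa_seq, "", fixed = TRUE), function(res) {
    paste(vapply(res, function(a) {
      cc <- .codons[[a]]
      if (is.null(cc)) "NNN" else cc[sample.int(length(cc), 1L)]
    }, character(1)), collapse = "")
  }, character(1))
}

#' Generate one synthetic repertoire sample
#'
#' Draws `n_clones` clones from a [lineage_profile()]: CDR3 length from the
#' profile's length law, residues i.i.d. from the background frequencies, a
#' forced apex-window Cys with probability `apex_cys_prob` (uniform position
#' within the clipped five-residue window), a forced position-2 Cys for Trbv1
#' clones when `trbv1_germline_cys`, a random codon back-translation for the
#' nucleotide clone key, and a heavy-tailed detection count. Deterministic
#' given `seed`; duplicate `(v_gene, cdr3_nt)` draws are merged by summing
#' counts.
#'
#' @param profile A `lineage_profile`.
#' @param seed Integer seed.
#' @param sample_id Sample identifier.
#' @param genotype Genotype label stored in the sample metadata.
#' @return A `repertoire_sample`.
#' @export
generate_sample <- function(profile, seed, sample_id = "synthetic",
                            genotype = "wild_type") {
  stopifnot(inherits(profile, "lineage_profile"))
  .with_seed(seed, {
    n <- profile$n_clones
    lens <- as.integer(sample(
      names(profile$cdr3_length_distribution), n, replace = TRUE,
      prob = profile$cdr3_length_distribution))
    v_gene <- sample(names(profile$v_gene_usage), n, replace = TRUE,
                     prob = profile$v_gene_usage)

    cdr3 <- vapply(lens, function(L) {
      paste(sample(names(profile$residue_freq), L, replace = TRUE,
                   prob = profile$residue_freq), collapse = "")
    }, character(1))

    # engineered apex-window Cys
    force_cys <- stats::runif(n) < profile$apex_cys_prob
    apex <- middle_position(lens)
    for (i in which(force_cys)) {
      win <- max(1L, apex[i] - 2L):min(lens[i], apex[i] + 2L)
      pos <- win[sample.int(length(win), 1L)]
      substr(cdr3[i], pos, pos) <- "C"
    }
    # Trbv1 germline Cys at CDR3 position 2
    if (profile$trbv1_germline_cys) {
      trbv1 <- v_gene == "TRBV1" & lens >= 2L
      substr(cdr3[trbv1], 2L, 2L) <- "C"
    }

    junction_aa <- paste0("C", cdr3,
                          sample(c("F", "W"), n, replace = TRUE,
                                 prob = c(0.9, 0.1)))
    cdr3_nt <- .back_translate(junction_aa)

    low <- stats::runif(n) < profile$singleton_fraction
    counts <- ifelse(low,
                     sample(1:2, n, replace = TRUE),
                     3L + stats::rgeom(n, profile$count_geom_prob))

    clones <- tibble(
      v_gene = v_gene, chain = profile$chain, cdr3_nt = cdr3_nt,
      junction_aa = junction_aa, cdr3_aa = cdr3,
      detection_count = as.integer(counts), productive = TRUE
    ) |>
      dplyr::group_by(.data$v_gene, .data$cdr3_nt) |>
      dplyr::summarise(
        dplyr::across(c("chain", "junction_aa", "cdr3_aa", "productive"),
                      dplyr::first),
        detection_count = sum(.data$detection_count),
        .groups = "drop"
      ) |>
      dplyr::arrange(.data$v_gene, .data$cdr3_nt)

    repertoire_sample(clones, sample_id = sample_id, chain = profile$chain,
                      lineage = profile$lineage, genotype = genotype)
  })
}

#' Study design for an end-to-end synthetic experiment
#'
#' Defaults emulate the wild-type enrichment pattern: CD8aa intestinal
#' intraepithelial lymphocytes (and their thymic precursors) are enriched for
#' apex-Cys CDR3s (6-10 percent), preselection thymocytes are intermediate,
#' and conventional T cells are depleted. Under attenuated TCR signaling or
#' MHC deficiency every lineage inherits the preselection apex-Cys
#' probability (a flat profile).
#'
#' @param genotype_effect `"wild_type"`, `"signaling_attenuated"` or
#'   `"mhc_deficient"`.
#' @param n_mice_per_group Samples per lineage.
#' @param seed Root seed; fully determines the study.
#' @param profiles Named list of [lineage_profile()]s keyed by lineage. The
#'   default covers preselection, CD4_Tconv, CD8_Tconv and CD8aaIEL with
#'   apex-Cys probabilities 0.03, 0.01, 0.01 and 0.08.
#' @param n_clones Clones per sample used in the default profiles.
#' @return A `study_config` list.
#' @export
study_config <- function(genotype_effect = "wild_type",
                         n_mice_per_group = 3L,
                         seed = 1L,
                         profiles = NULL,
                         n_clones = 5000L) {
  genotype_effect <- match.arg(
    genotype_effect, c("wild_type", "signaling_attenuated", "mhc_deficient"))
  if (is.null(profiles)) {
    probs <- c(preselection = 0.03, CD4_Tconv = 0.01,
               CD8_Tconv = 0.01, CD8aaIEL = 0.08)
    profiles <- purrr::imap(probs, function(p, lin) {
      lineage_profile(lineage = lin, n_clones = n_clones, apex_cys_prob = p)
    })
  }
  if (genotype_effect != "wild_type") {
    p0 <- profiles[["preselection"]]$apex_cys_prob
    profiles <- purrr::map(profiles, function(pr) {
      pr$apex_cys_prob <- p0
      pr
    })
  }
  structure(
    list(genotype_effect = genotype_effect,
         n_mice_per_group = as.integer(n_mice_per_group),
         seed = as.integer(seed), profiles = profiles),
    class = "study_config"
  )
}

#' Generate a full synthetic study
#'
#' Emits `n_mice_per_group` samples per lineage with the configured
#' enrichment pattern, plus a manifest of the true generating parameters.
#'
#' @param config A [study_config()].
#' @return List with `samples` (list of `repertoire_sample`) and `manifest`
#'   (tibble of true parameters, one row per sample).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  grid <- tidyr::expand_grid(
    lineage = names(config$profiles),
    mouse = seq_len(config$n_mice_per_group)
  )
  sample_seeds <- .with_seed(config$seed,
                             sample.int(2^31 - 1, nrow(grid)))
  samples <- purrr::pmap(
    list(grid$lineage, grid$mouse, sample_seeds),
    function(lin, mouse, s) {
      generate_sample(
        config$profiles[[lin]], seed = s,
        sample_id = sprintf("%s_%s_m%d", config$genotype_effect, lin, mouse),
        genotype = config$genotype_effect
      )
    }
  )
  manifest <- tibble(
    sample_id = vapply(samples, function(s) attr(s, "sample_id"),
                       character(1)),
    lineage = grid$lineage,
    genotype = config$genotype_effect,
    chain = vapply(samples, function(s) attr(s, "chain"), character(1)),
    mouse = grid$mouse,
    n_clones_drawn = vapply(grid$lineage, function(l)
      config$profiles[[l]]$n_clones, integer(1)),
    apex_cys_prob_true = vapply(grid$lineage, function(l)
      config$profiles[[l]]$apex_cys_prob, numeric(1)),
    singleton_fraction = vapply(grid$lineage, function(l)
      config$profiles[[l]]$singleton_fraction, numeric(1)),
    seed = sample_seeds
  )
  list(samples = samples, manifest = manifest)
}
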