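# End-to-end orchestration: quantify (build + filter feature tables),
# compare (Mann-Whitney comparisons, histograms, threshold percentages,
# overlap), usage (amino-acid composition), enrich (GO
# over-representation). A thin command-line wrapper around these lives in
# inst/cli/thermbond.R.

#' Pipeline configuration
#'
#' Collects the input paths and analysis parameters of a two-species run.
#' Defaults encode the canonical criteria: 3.5/2.5 A hydrogen-bond
#' cutoffs, 4.0 A salt-bridge cutoff, QMEAN minimum -5, upper fractions
#' 25% and 50%, histogram bin widths 0.25 (hydrogen bonds per amino acid)
#' and 0.01 (salt bridges per amino acid), alpha 0.05.
#'
#' @param fasta_a,fasta_b FASTA paths per species.
#' @param pdb_dir_a,pdb_dir_b Directories of PDB models, one file per
#'   protein, file base name = protein ID.
#' @param qmean_a,qmean_b Paths to per-protein metadata TSVs with columns
#'   protein_id and qmean.
#' @param annotations Optional protein-to-GO TSV path (for `run_enrich`).
#' @param species_a,species_b Species labels.
#' @param hb_params,sb_params Detection parameters.
#' @param qmean_min QMEAN filter threshold.
#' @param fractions Upper-quantile fractions to analyze.
#' @param bin_widths Named histogram bin widths for the two metrics.
#' @param alpha Significance level.
#' @param out_dir Optional output directory for TSV reports.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta_a, fasta_b, pdb_dir_a, pdb_dir_b,
                            qmean_a, qmean_b, annotations = NULL,
                            species_a = "species_a",
                            species_b = "species_b",
                            hb_params = hbond_params(),
                            sb_params = saltbridge_params(),
                            qmean_min = -5,
                            fractions = c(0.25, 0.5),
                            bin_widths = c(hbonds_per_aa = 0.25,
                                           saltbridges_per_aa = 0.01),
                            alpha = 0.05,
                            out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1, all(fractions > 0), all(fractions <= 1))
  structure(list(fasta_a = fasta_a, fasta_b = fasta_b,
                 pdb_dir_a = pdb_dir_a, pdb_dir_b = pdb_dir_b,
                 qmean_a = qmean_a, qmean_b = qmean_b,
                 annotations = annotations,
                 species_a = species_a, species_b = species_b,
                 hb_params = hb_params, sb_params = sb_params,
                 qmean_min = qmean_min, fractions = fractions,
                 bin_widths = bin_widths, alpha = alpha,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.read_qmean_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("protein_id", "qmean") %in% names(df))) {
    stop("metadata TSV must have columns protein_id and qmean: ", path)
  }
  df
}

.load_models <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(paths) == 0) stop("no .pdb files in ", dir)
  models <- lapply(paths, read_pdb)
  names(models) <- vapply(models, function(m) m$protein_id, character(1))
  models
}

#' Quantify: build and filter both species' feature tables
#'
#' @param config A `pipeline_config`.
#' @return List with filtered `feature_table`s `a` and `b`; each carries
#'   its `filter_log` attribute with the per-stage accounting. Feature and
#'   filter-log TSVs are written when `config$out_dir` is set. A species
#'   with zero surviving proteins is a hard error.
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  one <- function(fasta, pdb_dir, qmean_path, label) {
    seqs <- read_fasta(fasta)
    models <- .load_models(pdb_dir)
    qm <- .read_qmean_tsv(qmean_path)
    tab <- build_feature_table(seqs, models, qm,
                               hb_params = config$hb_params,
                               sb_params = config$sb_params,
                               species_label = label)
    apply_quality_filters(tab, qmean_min = config$qmean_min)
  }
  a <- one(config$fasta_a, config$pdb_dir_a, config$qmean_a,
           config$species_a)
  b <- one(config$fasta_b, config$pdb_dir_b, config$qmean_b,
           config$species_b)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("no proteins survive quality filtering for ",
         if (nrow(a) == 0) config$species_a else config$species_b)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(as.data.frame(a),
              file.path(config$out_dir, "features_a.tsv"))
    write_tsv(as.data.frame(b),
              file.path(config$out_dir, "features_b.tsv"))
    log <- rbind(cbind(species = config$species_a, attr(a, "filter_log")),
                 cbind(species = config$species_b, attr(b, "filter_log")))
    utils::write.table(log, file.path(config$out_dir, "filter_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(a = a, b = b)
}

.compare_row <- function(set, metric, xa, xb, alpha) {
  if (length(xa) < 3 || length(xb) < 3) {
    warning("comparison '", set, "' / ", metric,
            " skipped: fewer than 3 observations in a group")
    return(data.frame(set = set, metric = metric,
                      n1 = length(xa), n2 = length(xb),
                      median1 = stats::median(xa), median2 = stats::median(xb),
                      U = NA_real_, p_value = NA_real_,
                      significant = NA, stringsAsFactors = FALSE))
  }
  t <- mann_whitney_u(xa, xb)
  data.frame(set = set, metric = metric, n1 = t$n1, n2 = t$n2,
             median1 = stats::median(xa), median2 = stats::median(xb),
             U = t$statistic, p_value = t$p_value,
             significant = t$p_value < alpha, stringsAsFactors = FALSE)
}

#' Compare: species-level statistics on the filtered feature tables
#'
#' Emits one Mann-Whitney comparison per (protein set x metric): the full
#' sets, the ortholog pairs, and each configured upper fraction; plus the
#' within-species Spearman correlation between the two per-residue rates,
#' threshold percentages, frequency histograms, and the overlap between
#' the two species-A upper-half lists (hydrogen bonds vs salt bridges).
#'
#' @param tables List with feature tables `a` and `b` (from
#'   [run_quantify()] or built directly).
#' @param config A `pipeline_config`.
#' @return List with data frames `comparisons`, `correlations`,
#'   `histograms`, `thresholds`, and list `overlap`.
#' @export
run_compare <- function(tables, config) {
  a <- tables$a; b <- tables$b
  metrics <- c("hbonds_per_aa", "saltbridges_per_aa")
  alpha <- config$alpha

  rows <- list()
  for (m in metrics) {
    rows[[length(rows) + 1]] <- .compare_row("all", m, a[[m]], b[[m]], alpha)
  }
  orth <- pair_orthologs(a, b)
  for (m in metrics) {
    rows[[length(rows) + 1]] <-
      .compare_row("orthologs", m, orth[[paste0(m, "_a")]],
                   orth[[paste0(m, "_b")]], alpha)
  }
  for (f in config$fractions) {
    for (m in metrics) {
      ua <- upper_fraction(a, m, f)
      ub <- upper_fraction(b, m, f)
      rows[[length(rows) + 1]] <-
        .compare_row(sprintf("upper_%g%%", 100 * f), m, ua[[m]], ub[[m]],
                     alpha)
    }
  }
  comparisons <- do.call(rbind, rows)

  cor_rows <- lapply(list(a, b), function(tab) {
    ct <- tryCatch(spearman_rho(tab$hbonds_per_aa, tab$saltbridges_per_aa),
                   error = function(e) {
                     warning("rate correlation skipped for ",
                             attr(tab, "species_label"), ": ",
                             conditionMessage(e))
                     list(rho = NA_real_, p_value = NA_real_, n = nrow(tab))
                   })
    data.frame(species = attr(tab, "species_label"), rho = ct$rho,
               p_value = ct$p_value, n = ct$n, stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, cor_rows)

  hists <- list()
  for (tab in list(a, b)) {
    for (m in metrics) {
      h <- feature_histogram(tab, m, config$bin_widths[[m]])
      h$species <- attr(tab, "species_label")
      h$metric <- m
      hists[[length(hists) + 1]] <- h
    }
  }
  histograms <- do.call(rbind, hists)

  thr <- list()
  for (tab in list(a, b)) {
    for (m in metrics) {
      # report the share of proteins beyond the last full histogram bin of
      # the pooled range; callers can also call threshold_percentages()
      # directly with a threshold of interest
      cut <- max(feature_histogram(tab, m, config$bin_widths[[m]])$bin_low)
      tp <- threshold_percentages(tab, m, cut)
      thr[[length(thr) + 1]] <- data.frame(
        species = attr(tab, "species_label"), metric = m, threshold = cut,
        count = tp$count, n = nrow(tab), percent = tp$percent,
        stringsAsFactors = FALSE)
    }
  }
  thresholds <- do.call(rbind, thr)

  half_hb <- upper_fraction(a, "hbonds_per_aa", 0.5)
  half_sb <- upper_fraction(a, "saltbridges_per_aa", 0.5)
  overlap <- overlap_stats(half_hb, half_sb)

  out <- list(comparisons = comparisons, correlations = correlations,
              histograms = histograms, thresholds = thresholds,
              overlap = overlap)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("comparisons", "correlations", "histograms",
                 "thresholds")) {
      utils::write.table(out[[nm]],
                         file.path(config$out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Usage: amino-acid composition analyses over the standard protein sets
#'
#' Builds usage tables for the full filtered sets, each configured upper
#' fraction (by each metric), and the ortholog pairs, and computes the
#' hydrophobicity- and volume-rank correlations of the full-set usage
#' deviations.
#'
#' @param tables List with feature tables `a` and `b`.
#' @param config A `pipeline_config`.
#' @param ranks A `property_ranks` object (defaults to the bundled one).
#' @return List of `usage_table`s (named by protein set) plus
#'   `rank_correlations`.
#' @export
run_usage <- function(tables, config, ranks = property_ranks()) {
  a <- tables$a; b <- tables$b
  out <- list(all = count_usage(a, b))
  for (f in config$fractions) {
    for (m in c("hbonds_per_aa", "saltbridges_per_aa")) {
      nm <- sprintf("upper_%g%%_%s", 100 * f, m)
      out[[nm]] <- count_usage(upper_fraction(a, m, f),
                               upper_fraction(b, m, f))
    }
  }
  orth <- pair_orthologs(a, b)
  if (nrow(orth) > 0) {
    aa_cols_a <- paste0("aa_", .AA1_SORTED, "_a")
    aa_cols_b <- paste0("aa_", .AA1_SORTED, "_b")
    oa <- orth[aa_cols_a]; names(oa) <- paste0("aa_", .AA1_SORTED)
    ob <- orth[aa_cols_b]; names(ob) <- paste0("aa_", .AA1_SORTED)
    out$orthologs <- count_usage(oa, ob)
  }
  rc <- lapply(c("hydrophobicity", "volume"), function(w) {
    ct <- deviation_rank_correlation(out$all, ranks, w)
    data.frame(property = w, rho = ct$rho, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  })
  out$rank_correlations <- do.call(rbind, rc)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(cbind(term_id = out$all$residue, as.data.frame(out$all)),
              file.path(config$out_dir, "usage_all.tsv"))
  }
  out
}

#' Enrich: GO over-representation of the upper subsets
#'
#' Runs per-term Fisher exact over-representation of each configured upper
#' fraction (by each metric) of each species against that species' full
#' filtered table as background.
#'
#' @param tables List with feature tables `a` and `b`.
#' @param config A `pipeline_config` whose `annotations` path is set.
#' @return Named list of enrichment data frames
#'   (`<species>_upper_<pct>_<metric>`).
#' @export
run_enrich <- function(tables, config) {
  if (is.null(config$annotations)) {
    stop("config$annotations must point to a protein-to-GO TSV")
  }
  ann <- load_annotations(config$annotations)
  out <- list()
  for (sp in c("a", "b")) {
    tab <- tables[[sp]]
    for (f in config$fractions) {
      for (m in c("hbonds_per_aa", "saltbridges_per_aa")) {
        sel <- upper_fraction(tab, m, f)$protein_id
        nm <- sprintf("%s_upper_%g%%_%s", attr(tab, "species_label"),
                      100 * f, m)
        out[[nm]] <- enrich(sel, tab$protein_id, ann)
      }
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      if (nrow(out[[nm]]) > 0) {
        write_tsv(out[[nm]],
                  file.path(config$out_dir,
                            paste0("enrichment_",
                                   gsub("[^A-Za-z0-9_]", "_", nm),
                                   ".tsv")))
      }
    }
  }
  out
}
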