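# Per-protein feature tables: build, quality-filter, pair orthologs, and
# the subsetting/summary rules (upper quantiles, threshold percentages,
# histograms, list overlap) used in the species comparisons.

#' Construct a feature table
#'
#' @param df Data frame with one row per protein; must contain protein_id,
#'   annotation, length, qmean, n_hbonds, n_saltbridges, hbonds_per_aa,
#'   saltbridges_per_aa and the twenty `aa_*` count columns.
#' @param species_label Label stored on the table.
#' @return `df` with class `feature_table` and a `species_label` attribute.
#' @export
feature_table <- function(df, species_label = "species") {
  need <- c("protein_id", "annotation", "length", "qmean", "n_hbonds",
            "n_saltbridges", "hbonds_per_aa", "saltbridges_per_aa",
            paste0("aa_", .AA1_SORTED))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$protein_id)) {
    stop("protein_id must be unique within a feature table")
  }
  rownames(df) <- NULL
  attr(df, "species_label") <- species_label
  class(df) <- unique(c("feature_table", class(df)))
  df
}

.metric_arg <- function(metric) {
  match.arg(metric, c("hbonds_per_aa", "saltbridges_per_aa"))
}

# case-fold and collapse whitespace: makes "annotated exactly the same"
# operational for deduplication and ortholog pairing
.normalize_annotation <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

.count_aas <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  counts <- table(factor(ch, levels = .AA1_SORTED))
  as.integer(counts)
}

#' Build the per-protein feature table for one species
#'
#' Runs hydrogen-bond and salt-bridge detection on each model, counts amino
#' acids from the FASTA sequence, and normalizes both bond counts by the
#' full-length FASTA sequence length. The FASTA length is the denominator
#' even for multi-chain biounit models, which is why per-amino-acid rates
#' can exceed what a monomer would allow (a homodimer model contributes the
#' bonds of both chains against a single-chain length).
#'
#' @param seqs Data frame from [read_fasta()].
#' @param models Named list of `structure_model`s (names = protein IDs), or
#'   a list whose models carry their own `protein_id`.
#' @param qmeans Named numeric vector of QMEAN scores, or a data frame with
#'   columns protein_id and qmean.
#' @param hb_params,sb_params Detection parameter objects.
#' @param species_label Label stored on the table.
#' @return A `feature_table`. Sequences without a model are skipped with a
#'   warning (mirroring modeling failures); a model without a sequence is
#'   an error.
#' @export
build_feature_table <- function(seqs, models, qmeans,
                                hb_params = hbond_params(),
                                sb_params = saltbridge_params(),
                                species_label = "species") {
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    names(models) <- vapply(models, function(m) m$protein_id, character(1))
  }
  if (is.data.frame(qmeans)) {
    qm <- stats::setNames(qmeans$qmean, qmeans$protein_id)
  } else {
    qm <- qmeans
  }
  no_seq <- setdiff(names(models), seqs$protein_id)
  if (length(no_seq) > 0) {
    stop("models without a matching sequence: ",
         paste(no_seq, collapse = ", "))
  }
  no_qm <- setdiff(names(models), names(qm))
  if (length(no_qm) > 0) {
    stop("models without a QMEAN entry: ", paste(no_qm, collapse = ", "))
  }
  skipped <- setdiff(seqs$protein_id, names(models))
  if (length(skipped) > 0) {
    warning(length(skipped), " sequence(s) without a model skipped: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  }

  keep <- seqs[seqs$protein_id %in% names(models), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    id <- keep$protein_id[i]
    model <- models[[id]]
    n_hb <- nrow(detect_hbonds(model, hb_params))
    n_sb <- nrow(detect_salt_bridges(model, sb_params))
    len <- keep$length[i]
    counts <- .count_aas(keep$sequence[i])
    row <- data.frame(
      protein_id = id, annotation = keep$annotation[i], length = len,
      qmean = unname(qm[id]), n_hbonds = n_hb, n_saltbridges = n_sb,
      hbonds_per_aa = n_hb / len, saltbridges_per_aa = n_sb / len,
      stringsAsFactors = FALSE
    )
    row[paste0("aa_", .AA1_SORTED)] <- as.list(counts)
    row
  })
  feature_table(do.call(rbind, rows), species_label = species_label)
}

#' Apply the model-quality and annotation filters
#'
#' Mirrors the quality-control protocol of proteome-scale model surveys:
#' (1) among records sharing a normalized annotation string (case-folded,
#' whitespace-collapsed), keep only the record with the highest QMEAN (ties
#' broken by the lexicographically smallest protein ID); (2) drop records
#' with QMEAN strictly below `qmean_min` (a record at exactly the boundary
#' is kept); (3) drop records whose normalized annotation contains
#' "uncharacterized protein". The result carries a `filter_log` attribute
#' with the per-stage accounting. The filter is idempotent.
#'
#' @param table A `feature_table`.
#' @param qmean_min Minimum acceptable QMEAN (default -5).
#' @return The filtered `feature_table`.
#' @export
apply_quality_filters <- function(table, qmean_min = -5) {
  stopifnot(inherits(table, "feature_table"))
  label <- attr(table, "species_label")
  n_input <- nrow(table)

  norm <- .normalize_annotation(table$annotation)
  ord <- order(norm, -table$qmean, table$protein_id)
  tab <- table[ord, , drop = FALSE]
  tab <- tab[!duplicated(norm[ord]), , drop = FALSE]
  tab <- tab[order(tab$protein_id), , drop = FALSE]
  n_dedup <- nrow(tab)

  tab <- tab[tab$qmean >= qmean_min, , drop = FALSE]
  n_qmean <- nrow(tab)

  unchar <- grepl("uncharacterized protein",
                  .normalize_annotation(tab$annotation), fixed = TRUE)
  tab <- tab[!unchar, , drop = FALSE]
  n_final <- nrow(tab)

  log <- data.frame(
    stage = c("input", "unique_annotation", "qmean_pass",
              "uncharacterized_removed", "final"),
    n = c(n_input, n_dedup, n_qmean, sum(unchar), n_final)
  )
  if (n_final == 0) {
    message("apply_quality_filters: no records survive for ", label)
  }
  rownames(tab) <- NULL
  out <- feature_table(as.data.frame(tab), species_label = label)
  attr(out, "filter_log") <- log
  out
}

#' Pair orthologs between two filtered tables by identical annotation
#'
#' Proteins annotated exactly the same (after case-folding and whitespace
#' collapsing) in the two species are treated as an ortholog pair. Because
#' [apply_quality_filters()] leaves one record per annotation, at most one
#' pair exists per annotation string.
#'
#' @param a,b Filtered `feature_table`s.
#' @return A data frame with one row per pair: the shared normalized
#'   annotation plus the columns of both records suffixed `_a` / `_b`.
#' @export
pair_orthologs <- function(a, b) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  da <- as.data.frame(a)
  db <- as.data.frame(b)
  da$.ann <- .normalize_annotation(da$annotation)
  db$.ann <- .normalize_annotation(db$annotation)
  if (anyDuplicated(da$.ann) || anyDuplicated(db$.ann)) {
    stop("tables must be deduplicated (one record per annotation) before ",
         "ortholog pairing")
  }
  m <- merge(da, db, by = ".ann", suffixes = c("_a", "_b"))
  m <- m[order(m$.ann), , drop = FALSE]
  names(m)[names(m) == ".ann"] <- "annotation_key"
  rownames(m) <- NULL
  m
}

#' Upper fraction of a table by a per-residue bond rate
#'
#' Sorts descending by the metric (ties broken by ascending protein ID,
#' making the subset deterministic) and keeps the first
#' `ceiling(fraction * n)` records. With set sizes 482 and 58 this yields
#' upper-quartile/upper-half subsets of 121/241 and 15/29.
#'
#' @param table A `feature_table`.
#' @param metric `"hbonds_per_aa"` or `"saltbridges_per_aa"`.
#' @param fraction Fraction in (0, 1].
#' @return The subset as a `feature_table`.
#' @export
upper_fraction <- function(table, metric = "hbonds_per_aa", fraction) {
  stopifnot(inherits(table, "feature_table"), nrow(table) > 0)
  metric <- .metric_arg(metric)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  k <- ceiling(fraction * nrow(table))
  ord <- order(-table[[metric]], table$protein_id)
  out <- table[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  feature_table(as.data.frame(out),
                species_label = attr(table, "species_label"))
}

#' Count and percentage of proteins above a rate threshold
#'
#' Strictly-greater comparison ("more than"), percentage of the table size
#' rounded to one decimal.
#'
#' @param table A `feature_table`.
#' @param metric `"hbonds_per_aa"` or `"saltbridges_per_aa"`.
#' @param threshold Rate threshold.
#' @return List with `count` and `percent`.
#' @export
threshold_percentages <- function(table, metric = "hbonds_per_aa",
                                  threshold) {
  stopifnot(inherits(table, "feature_table"), nrow(table) > 0)
  metric <- .metric_arg(metric)
  count <- sum(table[[metric]] > threshold)
  list(count = count, percent = round(100 * count / nrow(table), 1))
}

#' Frequency histogram of a per-residue bond rate
#'
#' Half-open bins `[k*w, (k+1)*w)`; percents are rounded to one decimal and
#' sum to 100 within rounding.
#'
#' @param table A `feature_table`.
#' @param metric `"hbonds_per_aa"` or `"saltbridges_per_aa"`.
#' @param bin_width Positive bin width `w`.
#' @return Data frame with bin_low, bin_high, count, percent. Empty tables
#'   yield an empty histogram.
#' @export
feature_histogram <- function(table, metric = "hbonds_per_aa", bin_width) {
  stopifnot(inherits(table, "feature_table"))
  metric <- .metric_arg(metric)
  stopifnot(is.numeric(bin_width), bin_width > 0)
  v <- table[[metric]]
  if (length(v) == 0) {
    return(data.frame(bin_low = numeric(0), bin_high = numeric(0),
                      count = integer(0), percent = numeric(0)))
  }
  bin <- floor(v / bin_width)
  rng <- seq(min(bin), max(bin))
  count <- vapply(rng, function(k) sum(bin == k), integer(1))
  data.frame(
    bin_low = rng * bin_width,
    bin_high = (rng + 1) * bin_width,
    count = count,
    percent = round(100 * count / length(v), 1)
  )
}

#' Overlap between two protein lists
#'
#' @param a,b `feature_table`s (or data frames with a protein_id column)
#'   sharing an ID space.
#' @return List with `n_overlap` (size of the ID intersection) and
#'   `percent_of_union` (100 * intersection / union, rounded to the nearest
#'   integer; 0 for two empty lists).
#' @export
overlap_stats <- function(a, b) {
  ia <- unique(a$protein_id)
  ib <- unique(b$protein_id)
  n_int <- length(intersect(ia, ib))
  n_union <- length(union(ia, ib))
  list(n_overlap = n_int,
       percent_of_union = if (n_union == 0) 0 else
         round(100 * n_int / n_union))
}
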