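# Amino-acid composition accounting between two species' protein sets, and
# the residue-property (hydrophobicity / volume) rank correlations of the
# usage deviations.

#' Amino-acid usage table for two species
#'
#' Totals each residue over each species' proteins, then derives expected
#' counts from the standard 20 x 2 contingency expectations (row total x
#' column total / grand total), per-residue deviations (observed minus
#' expected, on raw counts) and use-rate differences in percentage points.
#' X residues are excluded from the 20-residue table and their count is
#' reported. Group membership flags mark the 11 residues most likely to
#' form conventional hydrogen bonds (S, T, N, Q, H, Y, W, D, E, R, K) and
#' the positively (R, K, H) and negatively (D, E) charged sets.
#'
#' @param seqs_a,seqs_b Per-species inputs: either a data frame from
#'   [read_fasta()] (sequences are counted) or a `feature_table` (the
#'   `aa_*` count columns are summed).
#' @return A data frame of class `usage_table` with one row per residue and
#'   columns residue, observed_a/b, expected_a/b, deviation_a/b,
#'   use_rate_delta, is_hbond_prone, is_positive, is_negative. Attributes:
#'   `test` (the chi-square result), `group_sums` (deviation and use-rate
#'   sums over the three residue groups), `n_x_excluded`.
#' @export
count_usage <- function(seqs_a, seqs_b) {
  count_set <- function(s) {
    if (inherits(s, "feature_table") ||
        all(paste0("aa_", .AA1_SORTED) %in% names(s))) {
      if (nrow(s) == 0) stop("empty species set")
      counts <- vapply(paste0("aa_", .AA1_SORTED),
                       function(cn) sum(s[[cn]]), numeric(1))
      names(counts) <- .AA1_SORTED
      list(counts = counts, n_x = 0L)
    } else if (!is.null(s$sequence)) {
      if (nrow(s) == 0) stop("empty species set")
      ch <- unlist(strsplit(s$sequence, ""), use.names = FALSE)
      counts <- table(factor(ch, levels = .AA1_SORTED))
      list(counts = stats::setNames(as.numeric(counts), .AA1_SORTED),
           n_x = sum(ch == "X"))
    } else {
      stop("species input must be a sequence data frame or a feature_table")
    }
  }
  ca <- count_set(seqs_a)
  cb <- count_set(seqs_b)
  n_x <- ca$n_x + cb$n_x
  if (n_x > 0) {
    message("count_usage: ", n_x,
            " X residue(s) excluded from the 20-residue table")
  }

  observed <- cbind(a = ca$counts, b = cb$counts)
  test <- chi_square_independence(observed)
  expected <- test$expected
  cs <- colSums(observed)

  out <- data.frame(
    residue = .AA1_SORTED,
    observed_a = observed[, "a"], observed_b = observed[, "b"],
    expected_a = expected[, "a"], expected_b = expected[, "b"],
    deviation_a = observed[, "a"] - expected[, "a"],
    deviation_b = observed[, "b"] - expected[, "b"],
    use_rate_delta = 100 * (observed[, "a"] / cs["a"] -
                            observed[, "b"] / cs["b"]),
    is_hbond_prone = .AA1_SORTED %in% .HBOND_PRONE,
    is_positive = .AA1_SORTED %in% .POSITIVE,
    is_negative = .AA1_SORTED %in% .NEGATIVE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL

  group_sums <- do.call(rbind, lapply(
    list(hbond_prone = .HBOND_PRONE, positive = .POSITIVE,
         negative = .NEGATIVE),
    function(g) {
      sel <- out$residue %in% g
      data.frame(deviation_a = sum(out$deviation_a[sel]),
                 use_rate_delta = sum(out$use_rate_delta[sel]))
    }))
  group_sums <- cbind(group = rownames(group_sums), group_sums)
  rownames(group_sums) <- NULL

  attr(out, "test") <- test
  attr(out, "group_sums") <- group_sums
  attr(out, "n_x_excluded") <- n_x
  class(out) <- c("usage_table", class(out))
  out
}

#' Residue property ranks (hydrophobicity and volume)
#'
#' The bundled defaults rank residues by the Kyte-Doolittle hydropathy
#' scale and by standard residue volumes, higher rank meaning more
#' hydrophobic / larger; ties in the underlying scales are broken
#' alphabetically so each rank set is a permutation of 1..20. Both tables
#' ship as editable two-column TSVs (residue, rank) under `extdata/` and
#' can be replaced by any file in the same format, since published rank
#' scales vary.
#'
#' @param hydrophobicity_path,volume_path Optional paths to replacement
#'   rank tables (TSV with columns residue, rank).
#' @return A list of class `property_ranks` with named integer vectors
#'   `hydrophobicity` and `volume` (each a permutation of 1..20 over the 20
#'   one-letter codes) and a `provenance` string.
#' @export
property_ranks <- function(hydrophobicity_path = NULL, volume_path = NULL) {
  read_ranks <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (!all(c("residue", "rank") %in% names(df))) {
      stop("rank table must have columns 'residue' and 'rank': ", path)
    }
    v <- stats::setNames(as.integer(df$rank), toupper(df$residue))
    if (!setequal(names(v), unname(.AA1_SORTED)) ||
        !setequal(v, seq_len(20))) {
      stop("rank table must assign a permutation of 1..20 to the 20 ",
           "canonical residues: ", path)
    }
    v[.AA1_SORTED]
  }
  default <- function(name) {
    system.file("extdata", name, package = "thermbond", mustWork = TRUE)
  }
  hp <- if (is.null(hydrophobicity_path)) {
    default("hydrophobicity_ranks.tsv")
  } else hydrophobicity_path
  vp <- if (is.null(volume_path)) default("volume_ranks.tsv") else volume_path
  structure(list(
    hydrophobicity = read_ranks(hp),
    volume = read_ranks(vp),
    provenance = paste0(
      if (is.null(hydrophobicity_path)) {
        "hydrophobicity: Kyte-Doolittle hydropathy ordering (bundled); "
      } else paste0("hydrophobicity: ", hydrophobicity_path, "; "),
      if (is.null(volume_path)) {
        "volume: standard residue-volume ordering (bundled)"
      } else paste0("volume: ", volume_path))
  ), class = "property_ranks")
}

#' Correlation of usage deviations with a residue property rank
#'
#' Spearman rank correlation over the 20 residues between the species-A
#' usage deviation (observed minus expected counts) and the chosen
#' property rank.
#'
#' @param usage A `usage_table` from [count_usage()].
#' @param ranks A `property_ranks` object.
#' @param which `"hydrophobicity"` or `"volume"`.
#' @return A `thermbond_cor` (rho, p_value, n = 20).
#' @export
deviation_rank_correlation <- function(usage, ranks,
                                       which = c("hydrophobicity",
                                                 "volume")) {
  which <- match.arg(which)
  stopifnot(inherits(usage, "usage_table"),
            inherits(ranks, "property_ranks"))
  rk <- ranks[[which]][usage$residue]
  spearman_rho(usage$deviation_a, rk)
}
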