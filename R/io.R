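#' Read a cohort count table
#'
#' TSV with header columns `condition`, `developed`, `transferred` (tab
#' separated, '.' decimal, UTF-8). Each valid row becomes a
#' [estimate_rate()]; malformed rows are rejected with their line numbers.
#'
#' @param path Path to the TSV file.
#' @return Named list of `rate_estimate` objects (names = condition). An
#'   empty file yields an empty list with a warning.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "developed", "transferred")
  if (!all(need %in% names(df)))
    stop("count table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) {
    warning("empty count table: ", path)
    return(list())
  }
  dev <- suppressWarnings(as.numeric(df$developed))
  trf <- suppressWarnings(as.numeric(df$transferred))
  bad <- which(is.na(dev) | is.na(trf) | dev != round(dev) |
                 trf != round(trf) | trf <= 0 | dev < 0 | dev > trf)
  if (length(bad))
    stop("malformed count rows at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  stats::setNames(
    lapply(seq_len(nrow(df)), function(i) estimate_rate(dev[i], trf[i])),
    df$condition)
}

#' Ratio of two term-development rates
#'
#' @param r1,r2 Rates as [estimate_rate()] objects or probabilities.
#' @return `r1 / r2` as a plain number.
#' @examples
#' rate_ratio(0.104, 0.434)  # ~0.24
#' @export
rate_ratio <- function(r1, r2) {
  r1 <- as_rate(r1, "r1")$rate; r2 <- as_rate(r2, "r2")$rate
  if (r2 == 0) stop("denominator rate is zero", call. = FALSE)
  r1 / r2
}

#' Read an expression study from fixture TSVs
#'
#' Counterpart of [write_fixtures()]: reads `expression.tsv` plus, when
#' present, `annotation.tsv`, `pairs.tsv` and `truth.tsv` from `dir`.
#'
#' @param dir Directory holding the fixture files.
#' @param scale Scale of the stored values (fixtures are written on the
#'   intensity scale).
#' @return An [expr_study()] (with `truth` attached when available).
#' @export
read_expression_study <- function(dir, scale = "intensity") {
  ex <- file.path(dir, "expression.tsv")
  if (!file.exists(ex)) stop("no expression.tsv under ", dir, call. = FALSE)
  df <- utils::read.delim(ex, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  ann <- NULL
  fa <- file.path(dir, "annotation.tsv")
  if (file.exists(fa)) ann <- utils::read.delim(fa, stringsAsFactors = FALSE)
  pairs <- NULL; groups <- NULL
  fp <- file.path(dir, "pairs.tsv")
  if (file.exists(fp)) {
    pm <- utils::read.delim(fp, stringsAsFactors = FALSE,
                            colClasses = "character")
    has_pair <- !is.na(pm$pair_id) & pm$pair_id != ""
    if (any(has_pair))
      pairs <- stats::setNames(pm$pair_id[has_pair], pm$sample_id[has_pair])
    if (!is.null(pm$condition) && any(pm$condition != ""))
      groups <- stats::setNames(pm$condition, pm$sample_id)
  }
  st <- expr_study(vals, annotation = ann, pairs = pairs, groups = groups,
                   scale = scale)
  ft <- file.path(dir, "truth.tsv")
  if (file.exists(ft)) st$truth <- utils::read.delim(ft, stringsAsFactors = FALSE)
  st
}

#' Write and read a run configuration
#'
#' A run configuration is a flat named list of parameters (seeds, sizes,
#' strategy choices, paths). It round-trips through YAML exactly, so a run
#' re-executed from its emitted configuration reproduces its outputs.
#'
#' @param config Named list.
#' @param path Destination YAML file.
#' @return `write_run_config` invisibly returns `path`; `read_run_config`
#'   returns the named list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  tmp <- paste0(path, ".tmp")
  yaml::write_yaml(config, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
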