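#' Two-group assignment of samples
#'
#' @param group1,group2 Character vectors of sample ids; disjoint.
#' @param respects_pairing Does the assignment place one member of every
#'   sibling pair in each group?
#' @return An object of class `group_assignment`.
#' @export
group_assignment <- function(group1, group2, respects_pairing = FALSE) {
  group1 <- as.character(group1); group2 <- as.character(group2)
  if (anyDuplicated(c(group1, group2)))
    stop("groups must be disjoint and free of duplicates", call. = FALSE)
  structure(list(group1 = group1, group2 = group2,
                 respects_pairing = isTRUE(respects_pairing)),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group1:", paste(x$group1, collapse = " "), "\n")
  cat("group2:", paste(x$group2, collapse = " "), "\n")
  invisible(x)
}

# Canonical key for duplicate detection / label-swap dedupe.
assignment_key <- function(samples, group1) {
  paste(sort(match(group1, samples)), collapse = ",")
}

#' Count two-group assignments in closed form
#'
#' `choose(n_samples, group_size)`, halved when the two groups are equal in
#' size and label-swapped partitions are to be counted once.
#'
#' @param n_samples Total number of samples.
#' @param group_size Size of the first group.
#' @param dedupe_label_swap Count `{A|B}` and `{B|A}` once when
#'   `group_size == n_samples / 2`?
#' @return Integer-valued count (as double, exact for the sizes in play).
#' @examples
#' count_assignments(16, 8, TRUE)   # 6435
#' count_assignments(24, 8, FALSE)  # 735471
#' @export
count_assignments <- function(n_samples, group_size, dedupe_label_swap = TRUE) {
  if (group_size < 0 || group_size > n_samples)
    stop("'group_size' must lie in [0, n_samples]", call. = FALSE)
  cnt <- choose(n_samples, group_size)
  if (dedupe_label_swap && 2 * group_size == n_samples) cnt <- cnt / 2
  cnt
}

#' Exhaustively enumerate two-group assignments
#'
#' All ways of splitting `samples` into a first group of `group_size` and a
#' second group of the remainder. With `pair_map`, only pairing-respecting
#' splits are produced: each sibling pair contributes exactly one sample to
#' each group (so `group_size` is the number of pairs). Label-swapped
#' partitions are counted once when `dedupe_label_swap` and the groups are
#' equal-sized.
#'
#' @param samples Character vector of sample ids.
#' @param group_size Size of group 1 (ignored when `pair_map` is given:
#'   then it is the number of pairs).
#' @param dedupe_label_swap See [count_assignments()].
#' @param pair_map Optional named character vector mapping sample id to
#'   sibling-pair id; `samples` must then be exactly the paired samples.
#' @return List of [group_assignment()] objects.
#' @examples
#' length(enumerate_assignments(letters[1:4], 2))  # 3
#' @export
enumerate_assignments <- function(samples, group_size,
                                  dedupe_label_swap = TRUE, pair_map = NULL) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (!is.null(pair_map)) {
    pm <- pair_map[samples]
    if (anyNA(pm)) stop("'pair_map' must cover all samples", call. = FALSE)
    pairs <- split(samples, pm)
    if (any(lengths(pairs) != 2L))
      stop("every sibling pair must name exactly two samples", call. = FALSE)
    P <- length(pairs)
    picks <- expand.grid(rep(list(c(1L, 2L)), P))
    out <- vector("list", nrow(picks))
    keep <- logical(nrow(picks))
    for (i in seq_len(nrow(picks))) {
      g1 <- vapply(seq_len(P), function(j) pairs[[j]][picks[i, j]], character(1))
      g2 <- setdiff(samples, g1)
      if (dedupe_label_swap && !(samples[1] %in% g1)) next
      keep[i] <- TRUE
      out[[i]] <- group_assignment(g1, g2, respects_pairing = TRUE)
    }
    return(out[keep])
  }
  n <- length(samples)
  if (group_size < 1 || group_size > n)
    stop("'group_size' must lie in [1, length(samples)]", call. = FALSE)
  cmb <- utils::combn(n, group_size)
  balanced <- dedupe_label_swap && 2 * group_size == n
  out <- vector("list", ncol(cmb))
  keep <- logical(ncol(cmb))
  for (i in seq_len(ncol(cmb))) {
    idx <- cmb[, i]
    if (balanced && idx[1] != 1L) next  # keep the half containing sample 1
    keep[i] <- TRUE
    out[[i]] <- group_assignment(samples[idx], samples[-idx])
  }
  out[keep]
}

#' Sample distinct two-group assignments uniformly
#'
#' Draws `k` distinct assignments uniformly without replacement from all
#' `count_assignments(...)` possibilities, by rejection of duplicates.
#' Reproducible under `seed`.
#'
#' @inheritParams enumerate_assignments
#' @param k Number of assignments to draw.
#' @param seed Optional integer seed (local to this call).
#' @param exclude Optional list of [group_assignment()]s to omit from the
#'   sampling frame (e.g. the true assignment).
#' @return List of `k` [group_assignment()] objects.
#' @export
sample_assignments <- function(samples, group_size, k, seed = NULL,
                               dedupe_label_swap = TRUE, exclude = NULL) {
  samples <- as.character(samples)
  n <- length(samples)
  total <- count_assignments(n, group_size, dedupe_label_swap) -
    length(exclude)
  if (k > total)
    stop("'k' exceeds the number of available assignments (", total, ")",
         call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  excl_keys <- vapply(exclude %||% list(),
                      function(a) {
                        g1 <- a$group1
                        if (dedupe_label_swap && 2 * group_size == n &&
                            !(samples[1] %in% g1)) g1 <- a$group2
                        assignment_key(samples, g1)
                      }, character(1))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (key in excl_keys) assign(key, TRUE, envir = seen)
  balanced <- dedupe_label_swap && 2 * group_size == n
  out <- vector("list", k)
  got <- 0L
  while (got < k) {
    idx <- sort(sample.int(n, group_size))
    if (balanced && idx[1] != 1L) idx <- sort(setdiff(seq_len(n), idx))
    key <- paste(idx, collapse = ",")
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    got <- got + 1L
    out[[got]] <- group_assignment(samples[idx], samples[-idx])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
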