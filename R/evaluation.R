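#' Score a detected-tree / stem pair
#'
#' A detected tree (crown apex) and a field stem are eligible to match only
#' if the relative height difference is below 30% of the stem height and the
#' leaning angle between apex and stem position — `atan(horizontal distance
#' / apex height)` from nadir — is below 15 degrees, both strictly. The
#' score of an eligible pair averages the two margins linearly:
#' `0.5 * (1 - |dh| / (0.3 * stem_height)) + 0.5 * (1 - lean / 15)`,
#' giving 1 for an apex exactly on the stem with identical height and
#' approaching 0 at either constraint boundary. The matching constraints
#' are the standard ones; this particular score form is this package's own
#' (symmetric, bounded) choice.
#'
#' @param apex_height detected apex height, metres (vectorized).
#' @param stem_height field-measured tree height, metres, positive.
#' @param horizontal_dist apex-to-stem planimetric distance, metres.
#' @return numeric score in (0, 1], or `NA_real_` for ineligible pairs.
#' @export
pair_score <- function(apex_height, stem_height, horizontal_dist) {
  if (any(stem_height <= 0)) stop("stem heights must be positive",
                                  call. = FALSE)
  dh_rel <- abs(apex_height - stem_height) / stem_height
  lean <- atan2(horizontal_dist, apex_height) * 180 / pi
  ok <- dh_rel < 0.30 & lean < 15
  score <- 0.5 * (1 - dh_rel / 0.30) + 0.5 * (1 - lean / 15)
  ifelse(ok, score, NA_real_)
}

#' Match detected trees to a stem map
#'
#' Builds the score matrix with [pair_score()] and selects the set of pairs
#' with maximum total score — each detection and each stem used at most
#' once — by the Hungarian assignment algorithm. Unmatched stems are
#' omission errors (OE); unmatched detections whose apex lies outside the
#' plot buffer ring are commission errors (CE). Detections in the buffer
#' exist only to complete border crowns and are never counted against
#' precision.
#'
#' @param detected data.table of detections: `tree_id`, `apex_x`, `apex_y`,
#'   `apex_height`, and optionally `in_buffer` (default `FALSE`).
#' @param stems stem map: `tree_id`, `x`, `y`, `height_m`.
#' @return a `match_result`: list with `pairs` (data.table `stem_id`,
#'   `detection_id`, `score`), `mt`, `oe`, `ce`, `total_score`.
#' @export
match_trees <- function(detected, stems) {
  det <- as.data.table(detected)
  st <- as.data.table(stems)
  if (!"in_buffer" %in% names(det)) det[, in_buffer := FALSE]
  nd <- nrow(det); ns <- nrow(st)
  if (nd == 0L || ns == 0L) {
    return(structure(list(
      pairs = data.table(stem_id = integer(), detection_id = integer(),
                         score = numeric()),
      mt = 0L, oe = ns, ce = sum(!det$in_buffer), total_score = 0),
      class = "match_result"))
  }
  s <- matrix(0, nd, ns)
  for (j in seq_len(ns)) {
    d <- sqrt((det$apex_x - st$x[j])^2 + (det$apex_y - st$y[j])^2)
    sc <- pair_score(det$apex_height, st$height_m[j], d)
    s[, j] <- fifelse(is.na(sc), 0, sc)
  }
  assign <- solve_max_assignment(s)
  ok <- assign$pairs[s[cbind(assign$pairs[, 1L], assign$pairs[, 2L])] > 0, ,
                     drop = FALSE]
  ord <- order(st$tree_id[ok[, 2L]], det$tree_id[ok[, 1L]])
  ok <- ok[ord, , drop = FALSE]
  pairs <- data.table(stem_id = st$tree_id[ok[, 2L]],
                      detection_id = det$tree_id[ok[, 1L]],
                      score = s[ok])
  matched_det <- ok[, 1L]
  structure(list(
    pairs = pairs,
    mt = nrow(pairs),
    oe = ns - nrow(pairs),
    ce = sum(!det$in_buffer[setdiff(seq_len(nd), matched_det)]),
    total_score = sum(pairs$score)), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> MT=%d OE=%d CE=%d total score %.3f\n",
              x$mt, x$oe, x$ce, x$total_score))
  invisible(x)
}

#' Recall, precision and F-score of a matching
#'
#' `Re = MT / (MT + OE)`, `Pr = MT / (MT + CE)`,
#' `F = 2 Re Pr / (Re + Pr)`. When `MT = 0` with errors present all three
#' are 0 (the harmonic-mean limit); a denominator of zero (no stems, or no
#' detections outside the buffer) yields `NA` for the affected score.
#'
#' @param m a `match_result` (or list with `mt`, `oe`, `ce`).
#' @return list with `recall`, `precision`, `f_score`.
#' @export
accuracy_scores <- function(m) {
  mt <- m$mt; oe <- m$oe; ce <- m$ce
  recall <- if (mt + oe == 0L) NA_real_ else mt / (mt + oe)
  precision <- if (mt + ce == 0L) NA_real_ else mt / (mt + ce)
  f <- if (is.na(recall) || is.na(precision)) NA_real_
       else if (recall + precision == 0) 0
       else 2 * recall * precision / (recall + precision)
  list(recall = recall, precision = precision, f_score = f)
}

# Maximum-total-score assignment on a non-negative score matrix, unmatched
# allowed at score 0. Pads to square and runs the O(n^3)
# potentials-and-augmenting-paths form of the Hungarian algorithm on the
# negated matrix. Returns all row/col pairs of the complete assignment;
# callers drop zero-score pairs.
solve_max_assignment <- function(s) {
  n <- max(nrow(s), ncol(s))
  a <- matrix(0, n, n)
  a[seq_len(nrow(s)), seq_len(ncol(s))] <- -s   # minimize negated score
  p <- hungarian_min(a)
  rows <- seq_len(n)
  keep <- rows <= nrow(s) & p <= ncol(s)
  list(pairs = cbind(rows[keep], p[keep]))
}

# Classic Hungarian algorithm (Jonker-Volgenant potentials formulation) for
# a square cost matrix; returns for each row its assigned column.
hungarian_min <- function(a) {
  n <- nrow(a)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j]) { minv[j] <- cur; way[j + 1L] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}
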