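#' Multivariate hypergeometric probability mass
#'
#' Probability of drawing exactly \code{a} up-regulated and \code{b}
#' down-regulated reactions when sampling \code{n} reactions without
#' replacement from a universe of \code{N} reactions containing \code{Kup}
#' up- and \code{Kdown} down-regulated ones:
#' \deqn{P(a,b) = \frac{\binom{K_{up}}{a}\binom{K_{down}}{b}
#'   \binom{N-K_{up}-K_{down}}{n-a-b}}{\binom{N}{n}}}
#' Computed with log-space binomial coefficients, so it is stable for large
#' universes. Arguments outside the support return 0.
#'
#' @param N universe size.
#' @param Kup,Kdown numbers of up-/down-regulated reactions in the universe.
#' @param n draw size.
#' @param a,b observed up/down counts in the draw (vectorised, recycled).
#' @return probability (vector).
#' @export
mvhgPmf <- function(N, Kup, Kdown, n, a, b) {
  stopifnot(N >= 0, Kup >= 0, Kdown >= 0, Kup + Kdown <= N, n >= 0, n <= N)
  len <- max(length(a), length(b))
  a <- rep_len(a, len); b <- rep_len(b, len)
  rest <- N - Kup - Kdown
  ok <- a >= 0 & b >= 0 & a <= Kup & b <= Kdown & a + b <= n &
    (n - a - b) <= rest
  out <- numeric(len)
  if (any(ok)) {
    lg <- lchoose(Kup, a[ok]) + lchoose(Kdown, b[ok]) +
      lchoose(rest, n - a[ok] - b[ok]) - lchoose(N, n)
    out[ok] <- exp(lg)
  }
  out
}

# shared tail machinery: sum pmf over {a >= ka, b <= kb}
.mvhgTail <- function(N, Kup, Kdown, n, ka, kb) {
  aVals <- seq.int(ka, min(Kup, n))
  if (ka > min(Kup, n)) return(0)
  tot <- 0
  for (a in aVals) {
    bMax <- min(kb, Kdown, n - a)
    if (bMax < 0) next
    bVals <- 0:bMax
    tot <- tot + sum(mvhgPmf(N, Kup, Kdown, n, a, bVals))
  }
  min(tot, 1)
}

#' Up-regulation tail probability of a minimal network
#'
#' Probability that a uniformly drawn size-\code{n} subset of the universe
#' contains at least \code{kup} up-regulated and at most \code{kdown}
#' down-regulated reactions — small when the network holds many up- and few
#' down-regulated reactions. In absolute mode the same tail, computed over
#' the high/low sets, scores highly-expressed networks.
#'
#' @inheritParams mvhgPmf
#' @param kup,kdown observed counts in the network.
#' @return probability in [0, 1].
#' @export
pUp <- function(N, Kup, Kdown, n, kup, kdown) {
  .mvhgTail(N, Kup, Kdown, n, kup, kdown)
}

#' Down-regulation tail probability of a minimal network
#'
#' Mirror of [pUp()]: at least \code{kdown} down-regulated and at most
#' \code{kup} up-regulated reactions.
#'
#' @inheritParams pUp
#' @return probability in [0, 1].
#' @export
pDown <- function(N, Kup, Kdown, n, kup, kdown) {
  .mvhgTail(N, Kdown, Kup, n, kdown, kup)
}

#' Score minimal networks against regulation sets
#'
#' For every network computes its size \code{n} counted within the universe
#' (helper demand reactions are excluded: they carry no GPR and occur in
#' every network), the up/down membership counts, their percentages, both
#' tail p-values, and a rank per task: ascending in the p-value of the
#' requested direction, ties broken by larger percentage in that direction,
#' then smaller network size, then network index.
#'
#' @param mins list of [MinNetwork-class].
#' @param sets a [RegulationSets-class] over the same pruned model.
#' @param rankBy \code{"up"} (default) or \code{"down"}; in absolute mode
#'   \code{"up"} ranks by high-expression enrichment.
#' @param exclude reaction ids to drop from each network before counting
#'   (beyond the automatic exclusion of anything outside the universe that
#'   is a known helper pattern, pass the demand ids here).
#' @param fdr add Benjamini-Hochberg adjusted columns \code{q_up},
#'   \code{q_down} (across the scored networks).
#' @return data.frame with columns \code{task_id}, \code{min_index},
#'   \code{size}, \code{n}, \code{k_up}, \code{k_down}, \code{pct_up},
#'   \code{pct_down}, \code{p_up}, \code{p_down}, \code{rank},
#'   \code{reactions}.
#' @export
scoreMins <- function(mins, sets, rankBy = c("up", "down"),
                      exclude = character(), fdr = FALSE) {
  rankBy <- match.arg(rankBy)
  N <- length(sets@universe)
  Kup <- length(sets@up); Kdown <- length(sets@down)
  cols <- c("task_id", "min_index", "size", "n", "k_up", "k_down",
            "pct_up", "pct_down", "p_up", "p_down", "rank", "reactions")
  if (!length(mins)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    return(df)
  }
  rec <- lapply(seq_along(mins), function(i) {
    m <- mins[[i]]
    rx <- setdiff(m@reactions, exclude)
    out <- setdiff(rx, sets@universe)
    if (length(out))
      stop(sprintf("network %d contains reaction(s) outside the universe: %s",
                   i, paste(out, collapse = ", ")), call. = FALSE)
    n <- length(rx)
    kup <- length(intersect(rx, sets@up))
    kdown <- length(intersect(rx, sets@down))
    data.frame(task_id = m@task, min_index = i, size = m@size, n = n,
               k_up = kup, k_down = kdown,
               pct_up = if (n) 100 * kup / n else 0,
               pct_down = if (n) 100 * kdown / n else 0,
               p_up = pUp(N, Kup, Kdown, n, kup, kdown),
               p_down = pDown(N, Kup, Kdown, n, kup, kdown),
               reactions = paste(sort(rx), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rec)
  p <- if (rankBy == "up") df$p_up else df$p_down
  pct <- if (rankBy == "up") df$pct_up else df$pct_down
  ord <- order(p, -pct, df$size, df$min_index)
  df$rank <- integer(nrow(df))
  df$rank[ord] <- seq_len(nrow(df))
  if (fdr) {
    df$q_up <- stats::p.adjust(df$p_up, method = "BH")
    df$q_down <- stats::p.adjust(df$p_down, method = "BH")
  }
  rownames(df) <- NULL
  df[, c(cols, setdiff(names(df), cols)), drop = FALSE]
}

#' Write an enrichment report
#'
#' Tab-delimited, one row per network, ordered by rank.
#'
#' @param records data.frame from [scoreMins()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEnrichment <- function(records, path) {
  if (nrow(records)) records <- records[order(records$rank), , drop = FALSE]
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
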