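#' Read a gene expression table
#'
#' Two-column tab-delimited text: gene id, value. A header line is detected
#' (second field non-numeric) and skipped. Relative profiles hold log2 fold
#' changes; absolute profiles hold RPKM/FPKM-like abundances. Rows with
#' \code{NA} values are skipped with a warning; duplicate gene rows are
#' collapsed by arithmetic mean with a warning. An optional two-column
#' mapping table translates gene ids (e.g. locus tags to the model's gene
#' ids) before collapsing.
#'
#' @param path file path.
#' @param mode \code{"foldchange"} or \code{"absolute"}.
#' @param mapping \code{NULL}, or path to a two-column tab-delimited file
#'   (from id, to id); unmapped genes keep their id.
#' @return an [ExpressionProfile-class].
#' @export
readExpression <- function(path, mode = c("foldchange", "absolute"),
                           mapping = NULL) {
  mode <- match.arg(mode)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop("expression file is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("expression file line %d: expected two tab-separated fields",
                 bad[1]), call. = FALSE)
  gene <- trimws(vapply(parts, `[[`, character(1), 1L))
  valTxt <- trimws(vapply(parts, `[[`, character(1), 2L))
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(valTxt[1]))) &&
      !valTxt[1] %in% c("NA", "na", "NaN"))
    start <- 2L                                  # header line
  gene <- gene[seq(start, length(gene))]
  valTxt <- valTxt[seq(start, length(valTxt))]
  isNA <- valTxt %in% c("NA", "na", "NaN", "")
  val <- suppressWarnings(as.numeric(valTxt))
  nonNum <- which(!isNA & is.na(val))
  if (length(nonNum))
    stop(sprintf("expression file line %d: non-numeric value '%s'",
                 nonNum[1] + start - 1L, valTxt[nonNum[1]]), call. = FALSE)
  if (any(isNA)) {
    warning(sprintf("skipping %d row(s) with NA values", sum(isNA)))
    gene <- gene[!isNA]; val <- val[!isNA]
  }
  if (!length(gene))
    stop("expression file has no usable rows: ", path, call. = FALSE)
  if (!is.null(mapping)) {
    mp <- utils::read.table(mapping, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("from", "to"))
    hit <- match(gene, mp$from)
    gene[!is.na(hit)] <- mp$to[hit[!is.na(hit)]]
  }
  if (anyDuplicated(gene)) {
    warning(sprintf("collapsing %d duplicate gene id(s) by mean",
                    sum(duplicated(gene))))
    agg <- tapply(val, gene, mean)
    # keep first-appearance order
    ord <- unique(gene)
    val <- as.numeric(agg[ord]); gene <- ord
  }
  methods::new("ExpressionProfile", mode = mode,
               values = stats::setNames(val, gene))
}

#' Map expression onto reactions and call regulation sets
#'
#' Evaluates every GPR rule against the profile ([gprValue()]; and = min,
#' or = max) and partitions the model's reactions.
#'
#' In relative (fold change) mode a reaction is up-regulated when its value
#' clears \code{upCutoff} (default +1 log2 unit, i.e. 2-fold) and
#' down-regulated when it falls below \code{downCutoff} (default -1).
#' In absolute mode the high/low sets are the upper/lower percentile tails
#' (defaults 75th/25th) of the valued reactions, percentiles computed with
#' linear interpolation over valued reactions only; ties at the cutoff fall
#' into the extreme set.
#'
#' Reactions without GPR, or whose genes are all unmeasured, are neutral. By
#' default they still count in the universe N (they dilute enrichment);
#' \code{universe = "valued"} restricts N to reactions with a defined value.
#'
#' @param model a pruned [MetabolicModel-class].
#' @param profile an [ExpressionProfile-class].
#' @param upCutoff,downCutoff fold-change thresholds (relative mode only).
#' @param highPct,lowPct percentile cutoffs in [0, 100] (absolute mode only).
#' @param universe \code{"all"} or \code{"valued"}.
#' @return a [RegulationSets-class].
#' @export
regulationSets <- function(model, profile, upCutoff = NULL, downCutoff = NULL,
                           highPct = NULL, lowPct = NULL,
                           universe = c("all", "valued")) {
  universe <- match.arg(universe)
  relArgs <- !is.null(upCutoff) || !is.null(downCutoff)
  absArgs <- !is.null(highPct) || !is.null(lowPct)
  if (profile@mode == "foldchange" && absArgs)
    stop("percentile cutoffs (highPct/lowPct) apply to absolute mode only",
         call. = FALSE)
  if (profile@mode == "absolute" && relArgs)
    stop("fold-change cutoffs (upCutoff/downCutoff) apply to relative mode only",
         call. = FALSE)
  vals <- reactionExpression(model, profile)
  valued <- !is.na(vals)
  uni <- if (universe == "all") names(vals) else names(vals)[valued]
  if (profile@mode == "foldchange") {
    if (is.null(upCutoff)) upCutoff <- 1
    if (is.null(downCutoff)) downCutoff <- -1
    up <- names(vals)[valued & vals >= upCutoff]
    down <- names(vals)[valued & vals <= downCutoff]
    settings <- list(upCutoff = upCutoff, downCutoff = downCutoff)
  } else {
    if (is.null(highPct)) highPct <- 75
    if (is.null(lowPct)) lowPct <- 25
    vv <- vals[valued]
    if (length(vv)) {
      qHi <- stats::quantile(vv, highPct / 100, type = 7, names = FALSE)
      qLo <- stats::quantile(vv, lowPct / 100, type = 7, names = FALSE)
      up <- names(vv)[vv >= qHi]
      down <- names(vv)[vv <= qLo]
      down <- setdiff(down, up)   # degenerate distributions: high wins
    } else up <- down <- character()
    settings <- list(highPct = highPct, lowPct = lowPct)
  }
  methods::new("RegulationSets", universe = uni, up = up, down = down,
               mode = profile@mode, settings = settings)
}

#' Reaction-level expression values
#'
#' GPR-mapped expression per reaction: \code{NA} for reactions without GPR
#' or with no measured gene.
#'
#' @param model a [MetabolicModel-class].
#' @param profile an [ExpressionProfile-class].
#' @return named numeric vector over all reactions.
#' @export
reactionExpression <- function(model, profile) {
  rules <- gprRules(model)
  vapply(rules, gprValue, numeric(1), values = profile@values)
}
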