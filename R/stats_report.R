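# Compartment-resolved statistics: strain and displacement summaries per
# chromatin-density bin and perinucleolar shell, and the group tests used
# to compare them (one-way ANOVA with Tukey HSD, binned t-test, boxplot
# summaries with a 3-sigma outlier rule).

.regionMean <- function(map, sel, absolute = FALSE) {
  v <- map[sel]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  if (absolute) mean(abs(v)) else mean(v)
}

#' Per-compartment strain statistics
#'
#' Mean hydrostatic strain per chromatin-density compartment C1..Cn and
#' the nucleolus (NLL), evaluated over the member pixels of a per-pixel
#' strain map (typically at peak deformation, the last stimulation
#' frame). Mode "absolute" averages |strain| (extension and compression
#' add up); "total" averages the signed strain (they cancel).
#'
#' @param strainMap per-pixel strain matrix (from [upsampleToImage()]).
#' @param labels a [CompartmentLabels-class] aligned with the map.
#' @param mode "absolute" or "total".
#' @return data.frame with columns compartment, value, nPixels; empty
#'   compartments are flagged by `NA` values.
#' @export
compartmentStrainStats <- function(strainMap, labels,
                                   mode = c("absolute", "total")) {
  mode <- match.arg(mode)
  if (!all(dim(strainMap) == dim(labels@densityLabels)))
    stop("strain map and labels are not geometrically aligned")
  absolute <- mode == "absolute"
  bins <- sort(unique(labels@densityLabels[labels@densityLabels > 0]))
  rows <- lapply(bins, function(b) {
    sel <- labels@densityLabels == b
    data.frame(compartment = sprintf("C%d", b),
               value = .regionMean(strainMap, sel, absolute),
               nPixels = sum(sel))
  })
  if (any(labels@nucleolusMask)) {
    rows[[length(rows) + 1]] <- data.frame(
      compartment = "NLL",
      value = .regionMean(strainMap, labels@nucleolusMask, absolute),
      nPixels = sum(labels@nucleolusMask))
  }
  out <- do.call(rbind, rows)
  out$mode <- mode
  out
}

#' Displacement statistics for nucleolus, shells and whole nucleus
#'
#' Mean displacement magnitude per region: nucleolus (NLL), perinucleolar
#' shells PC1..PCn and the whole lamina-excluded interior (NUC).
#'
#' @param dispMap per-pixel displacement-magnitude matrix (um), e.g. from
#'   [displacementMagnitudeMap()].
#' @param labels a [CompartmentLabels-class].
#' @return data.frame with columns region, value, nPixels.
#' @export
shellDisplacementStats <- function(dispMap, labels) {
  if (!all(dim(dispMap) == dim(labels@shellLabels)))
    stop("displacement map and labels are not geometrically aligned")
  rows <- list(data.frame(region = "NLL",
                          value = .regionMean(dispMap, labels@nucleolusMask),
                          nPixels = sum(labels@nucleolusMask)))
  for (k in seq_len(max(labels@shellLabels))) {
    sel <- labels@shellLabels == k
    rows[[length(rows) + 1]] <- data.frame(
      region = sprintf("PC%d", k),
      value = .regionMean(dispMap, sel), nPixels = sum(sel))
  }
  rows[[length(rows) + 1]] <- data.frame(
    region = "NUC", value = .regionMean(dispMap, labels@interiorMask),
    nPixels = sum(labels@interiorMask))
  do.call(rbind, rows)
}

#' Boxplot summary with a 3-sigma outlier rule
#'
#' 25th/75th percentile box with whiskers spanning the full data range
#' after excluding outliers more than 3 standard deviations from the
#' group mean.
#'
#' @param x numeric vector.
#' @return named list: median, q25, q75, whiskerLow, whiskerHigh,
#'   outliers, n.
#' @export
boxplotStats <- function(x) {
  x <- x[is.finite(x)]
  mu <- mean(x); sdv <- stats::sd(x)
  keep <- if (is.finite(sdv) && sdv > 0) abs(x - mu) <= 3 * sdv else
    rep(TRUE, length(x))
  q <- stats::quantile(x[keep], c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q25 = q[1], q75 = q[3],
       whiskerLow = min(x[keep]), whiskerHigh = max(x[keep]),
       outliers = x[!keep], n = length(x))
}

#' Group comparisons across compartments
#'
#' One-way ANOVA across groups with Tukey HSD pairwise adjusted p-values
#' (Tukey-Kramer for unequal n), a two-tailed unpaired t-test for an
#' optional binned comparison (e.g. light C1-C3 versus dense C4-C7), and
#' boxplot summaries per group. Identical groups (zero variance
#' everywhere) are reported as F = 0, p = 1.
#'
#' @param values numeric observations (typically one mean per nucleus and
#'   compartment).
#' @param groups factor or character of the same length.
#' @param binA,binB optional character vectors of group names defining
#'   the binned t-test contrast.
#' @return list with elements anova (F, p, df), tukey (data.frame of
#'   pairwise contrasts), tTest (or NULL), boxplots (per group).
#' @export
groupTests <- function(values, groups, binA = NULL, binB = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("need >= 2 observations per group")
  boxes <- lapply(split(values, groups), boxplotStats)
  if (stats::var(values) < .Machine$double.eps) {
    lev <- levels(groups)
    pairs <- utils::combn(lev, 2)
    tukey <- data.frame(contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
                        diff = 0, pAdj = 1)
    tt <- if (!is.null(binA)) list(statistic = 0, p = 1) else NULL
    return(list(anova = list(F = 0, p = 1,
                             df = c(nlevels(groups) - 1,
                                    length(values) - nlevels(groups))),
                tukey = tukey, tTest = tt, boxplots = boxes))
  }
  df <- data.frame(value = values, group = groups)
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      pAdj = tk[, "p adj"], row.names = NULL)
  tt <- NULL
  if (!is.null(binA) && !is.null(binB)) {
    a <- values[groups %in% binA]
    b <- values[groups %in% binB]
    ht <- stats::t.test(a, b, alternative = "two.sided")
    tt <- list(statistic = unname(ht$statistic), p = ht$p.value,
               meanA = mean(a), meanB = mean(b))
  }
  list(anova = list(F = an[1, "F value"], p = an[1, "Pr(>F)"],
                    df = an[, "Df"]),
       tukey = tukey, tTest = tt, boxplots = boxes)
}
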