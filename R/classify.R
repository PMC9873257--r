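## Group-comparison statistics and effect-strength classification of
## genotype screens: ANOVA gate, Dunnett many-to-one comparisons,
## min-of-two-controls effect sizes, and the strong/moderate/weak/none
## classification against a reference genotype's maximal effect.

#' One-way ANOVA gate
#'
#' Standard one-way fixed-effects ANOVA across the supplied groups, used as
#' the gate that decides whether a genotype has any effect at any light
#' intensity before its strength is classified. When all values are
#' identical in every group the test is degenerate and `p = 1` is returned
#' by convention.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `p`, `significant` (`p < alpha`).
#' @export
#' @examples
#' anovaGate(list(a = c(1, 2, 1.5), b = c(5, 6, 5.5)))
anovaGate <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need at least 2 groups with at least 2 values each",
         call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0)
    return(list(F = 0, p = 1, significant = FALSE))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  p <- fit$p.value
  if (is.nan(p)) p <- 1
  list(F = unname(fit$statistic), p = p, significant = p < alpha)
}

#' Dunnett many-to-one comparisons
#'
#' Two-sided comparisons of one experimental group against each control
#' with family-wise error control, using the pooled error term across all
#' groups and the multivariate-t distribution of the maximum statistic.
#' With a single control the comparison reduces to a pooled two-sample
#' t-test with no adjustment.
#'
#' @param experimental numeric vector of experimental-group values.
#' @param controls list of numeric control-group vectors (named or not).
#' @return data.frame with one row per control: `control`, `estimate`
#'   (experimental minus control mean), `t`, `df`, `p_raw` (unadjusted
#'   two-sided), `p_adj` (Dunnett-adjusted; `p_adj >= p_raw` always).
#' @export
#' @examples
#' set.seed(1)
#' dunnettCompare(rnorm(10, 2), list(c1 = rnorm(10), c2 = rnorm(10)))
dunnettCompare <- function(experimental, controls) {
  if (!is.list(controls)) controls <- list(controls)
  m <- length(controls)
  if (m < 1L) stop("need at least one control group", call. = FALSE)
  if (is.null(names(controls)) || any(!nzchar(names(controls))))
    names(controls) <- paste0("control_", seq_len(m))
  groups <- c(list(experimental), controls)
  if (any(lengths(groups) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  ns <- lengths(groups)
  N <- sum(ns)
  k <- length(groups)
  df <- N - k
  mus <- vapply(groups, mean, numeric(1))
  ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  s2 <- ss / df
  n0 <- ns[1]
  est <- mus[1] - mus[-1]
  se <- sqrt(s2 * (1 / n0 + 1 / ns[-1]))
  tt <- est / se
  p_raw <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  if (m == 1L) {
    p_adj <- p_raw
  } else {
    ## correlation of the comparison statistics (shared experimental group)
    inv <- 1 / n0 + 1 / ns[-1]
    R <- outer(seq_len(m), seq_len(m), function(i, j)
      (1 / n0) / sqrt(inv[i] * inv[j]))
    diag(R) <- 1
    p_adj <- vapply(abs(tt), function(ti) {
      1 - mvtnorm::pmvt(lower = rep(-ti, m), upper = rep(ti, m), df = df,
                        corr = R, algorithm =
                          mvtnorm::GenzBretz(abseps = 1e-5))[1]
    }, numeric(1))
    p_adj <- pmax(pmin(p_adj, 1), p_raw)  # numerical guard
  }
  data.frame(control = names(controls), estimate = unname(est),
             t = unname(tt), df = df, p_raw = unname(p_raw),
             p_adj = unname(p_adj), row.names = NULL)
}

#' Min-of-two-controls effect size
#'
#' The experimental effect is the smaller of the two mean differences
#' between the experimental group and each control, signed by their common
#' direction. When the two control comparisons disagree in sign the effect
#' is zero (screens of this kind assume consistent directions; a straddled
#' experimental mean is no effect).
#'
#' @param experimental,control_1,control_2 numeric vectors of per-trial
#'   values.
#' @return signed scalar effect in the units of the measurements.
#' @export
#' @examples
#' effectSize(rep(10, 3), rep(2, 3), rep(6, 3))  # 4
effectSize <- function(experimental, control_1, control_2) {
  if (!length(experimental) || !length(control_1) || !length(control_2))
    stop("groups must be non-empty", call. = FALSE)
  d1 <- mean(experimental) - mean(control_1)
  d2 <- mean(experimental) - mean(control_2)
  if (d1 == 0 || d2 == 0 || sign(d1) != sign(d2)) return(0)
  sign(d1) * min(abs(d1), abs(d2))
}

#' Classify effect strength against a reference maximum
#'
#' Normalizes a genotype's maximal effect over light intensities by the
#' reference genotype's maximal effect and assigns the class: `"none"` when
#' the ANOVA gate fails; otherwise `"strong"` (normalized effect >= 0.8),
#' `"moderate"` (>= 0.4), or `"weak"` (significant but < 0.4). The
#' classification is invariant to common rescaling of all measurements.
#'
#' @param effects numeric vector of per-intensity signed effects (from
#'   [effectSize()]).
#' @param gate_p p-value of the [anovaGate()] for this genotype/behavior.
#' @param reference_max maximal absolute effect of the reference genotype
#'   (> 0; a zero reference makes the classification undefined and returns
#'   `NA` markers).
#' @param alpha gate significance level (default 0.05).
#' @return data.frame with one row: `gate_p`, `effect` (maximal absolute
#'   effect), `normalized_effect`, `class`.
#' @export
#' @examples
#' classifyEffect(c(2, 4.5), gate_p = 0.001, reference_max = 5)
classifyEffect <- function(effects, gate_p, reference_max, alpha = 0.05) {
  if (is.na(reference_max) || reference_max == 0)
    return(data.frame(gate_p = gate_p, effect = NA_real_,
                      normalized_effect = NA_real_, class = NA_character_))
  eff <- max(abs(effects))
  norm <- eff / abs(reference_max)
  cls <- if (gate_p >= alpha) "none"
  else if (norm >= 0.8) "strong"
  else if (norm >= 0.4) "moderate"
  else "weak"
  data.frame(gate_p = gate_p, effect = eff, normalized_effect = norm,
             class = cls)
}

#' Classify a whole genotype screen
#'
#' End-to-end classification of a long-format measurement table: for each
#' behavior and experimental genotype, runs the ANOVA gate over all
#' genotype-by-intensity cells (experimental plus both controls), computes
#' the min-of-two-controls effect at each intensity, normalizes the maximal
#' effect by the reference genotype's maximal effect on that behavior, and
#' assigns the class.
#'
#' @param measurements data.frame with columns `behavior`, `genotype`,
#'   `intensity`, `value` (one row per trial).
#' @param experimental character vector of experimental genotype labels.
#' @param control_1,control_2 control genotype labels (driver-only,
#'   effector-only).
#' @param reference reference genotype label (maximal-effect line).
#' @param alpha gate significance level.
#' @return data.frame with one row per behavior x experimental genotype:
#'   `behavior`, `genotype`, `gate_p`, `effect`, `normalized_effect`,
#'   `class`.
#' @export
classifyScreen <- function(measurements, experimental, control_1,
                           control_2, reference, alpha = 0.05) {
  need <- c("behavior", "genotype", "intensity", "value")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns behavior, genotype, intensity, value",
         call. = FALSE)
  getCell <- function(b, g, i)
    measurements$value[measurements$behavior == b &
                         measurements$genotype == g &
                         measurements$intensity == i]
  out <- list()
  for (b in unique(measurements$behavior)) {
    ints <- unique(measurements$intensity[measurements$behavior == b])
    ref_eff <- vapply(ints, function(i)
      effectSize(getCell(b, reference, i), getCell(b, control_1, i),
                 getCell(b, control_2, i)), numeric(1))
    ref_max <- max(abs(ref_eff))
    for (g in experimental) {
      cells <- list()
      for (gg in c(g, control_1, control_2))
        for (i in ints)
          cells[[paste(gg, i)]] <- getCell(b, gg, i)
      gate <- anovaGate(cells, alpha = alpha)
      eff <- vapply(ints, function(i)
        effectSize(getCell(b, g, i), getCell(b, control_1, i),
                   getCell(b, control_2, i)), numeric(1))
      rec <- classifyEffect(eff, gate$p, ref_max, alpha = alpha)
      out[[paste(b, g)]] <- cbind(data.frame(behavior = b, genotype = g),
                                  rec)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Behavior-by-genotype class matrix
#'
#' Reshapes a [classifyScreen()] result into the color-codeable summary
#' matrix (behaviors as rows, genotypes as columns, classes as entries).
#'
#' @param records data.frame from [classifyScreen()].
#' @return character matrix of classes.
#' @export
effectMatrix <- function(records) {
  behaviors <- unique(records$behavior)
  genotypes <- unique(records$genotype)
  m <- matrix(NA_character_, length(behaviors), length(genotypes),
              dimnames = list(behaviors, genotypes))
  for (i in seq_len(nrow(records)))
    m[records$behavior[i], records$genotype[i]] <- records$class[i]
  m
}
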