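## Cross outcome enumeration under lethal biallelic mosaicism (LBM) and
## goodness-of-fit statistics for observed F1 counts.
##
## The sex-sorting cross: a gRNA line targeting an essential gene is crossed
## to a Cas9 line whose nuclease is Y-linked, X-linked or autosomal.
## Offspring that somatically carry both Cas9 and the gRNA suffer widespread
## biallelic disruption of the essential target and die; the Cas9 linkage
## therefore decides which sex survives.

#' Design of an F1 sexing/selection cross
#'
#' @param mother Zygosity of the gRNA mother: `"het"` (gRNA over a balancer)
#'   or `"hom"` (homozygous gRNA).
#' @param father Cas9 linkage of the father: `"none"` (wild type), `"Y"`
#'   (hemizygous Y-linked Cas9), `"X"` (hemizygous X-linked Cas9), or
#'   `"autosomal"` (homozygous autosomal Cas9).
#' @param maternal_cas9 If TRUE the mother carries Cas9 and deposits it in all
#'   eggs, so every gRNA-bearing offspring is subject to lethality regardless
#'   of paternal genotype.
#' @return A `cross_design`.
#' @export
cross_design <- function(mother = c("het", "hom"),
                         father = c("none", "Y", "X", "autosomal"),
                         maternal_cas9 = FALSE) {
  mother <- match.arg(mother)
  father <- match.arg(father)
  structure(list(mother = mother, father = father,
                 maternal_cas9 = isTRUE(maternal_cas9)),
            class = "cross_design")
}

#' Enumerate F1 classes of a sexing cross under lethal biallelic mosaicism
#'
#' Punnett-square enumeration of the F1 (sex x gRNA inheritance), followed by
#' the viability filter: a class whose members somatically carry at least one
#' Cas9 allele and at least one gRNA allele survives with probability
#' `1 - penetrance`. With a Y-linked Cas9 father all sons carry Cas9 (and
#' transheterozygous sons die); with an X-linked father all daughters do; with
#' an autosomal homozygous father every offspring does.
#'
#' @param cross A `cross_design`.
#' @param penetrance Lethality penetrance in transheterozygotes (0-1).
#' @return A data.frame with one row per pre-viability class: `class`, `sex`,
#'   `grna` (logical), `pre_prob` (Mendelian), `cas9` (logical), `lethal`,
#'   `surv_prob` (renormalized over survivors; all zero when every class is
#'   lethal — see attribute `"all_lethal"`).
#' @export
enumerate_f1 <- function(cross, penetrance = 1.0) {
  stopifnot(inherits(cross, "cross_design"),
            penetrance >= 0, penetrance <= 1)
  p_grna <- if (cross$mother == "hom") c(`TRUE` = 1.0) else c(`TRUE` = 0.5, `FALSE` = 0.5)
  classes <- expand.grid(sex = c("F", "M"), grna = as.logical(names(p_grna)),
                         stringsAsFactors = FALSE)
  classes$pre_prob <- 0.5 * p_grna[as.character(classes$grna)]
  classes$cas9 <- switch(cross$father,
                         none = rep(FALSE, nrow(classes)),
                         Y = classes$sex == "M",
                         X = classes$sex == "F",
                         autosomal = rep(TRUE, nrow(classes)))
  if (cross$maternal_cas9) classes$cas9 <- TRUE
  classes$lethal <- classes$cas9 & classes$grna
  classes$surv_weight <- classes$pre_prob * ifelse(classes$lethal, 1 - penetrance, 1)
  tot <- sum(classes$surv_weight)
  all_lethal <- tot == 0
  classes$surv_prob <- if (all_lethal) 0 else classes$surv_weight / tot
  classes$surv_weight <- NULL
  classes$class <- paste0(classes$sex, "/gRNA", ifelse(classes$grna, "+", "-"))
  classes <- classes[order(classes$sex, !classes$grna), c("class", "sex", "grna",
                                                          "pre_prob", "cas9",
                                                          "lethal", "surv_prob")]
  rownames(classes) <- NULL
  attr(classes, "all_lethal") <- all_lethal
  classes
}

#' Chi-squared goodness of fit for observed class counts
#'
#' Pearson's statistic against stated expected proportions, with a one-tailed
#' (upper) p-value, as used for segregation-ratio tests.
#'
#' @param observed Integer vector of class counts (sum > 0).
#' @param expected Expected proportions (same length; sums to 1). Default:
#'   equal proportions.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chisq_gof <- function(observed, expected = NULL) {
  stopifnot(is.numeric(observed), all(observed >= 0))
  n <- sum(observed)
  if (n <= 0) stop("total observed count must be positive")
  k <- length(observed)
  if (is.null(expected)) expected <- rep(1 / k, k)
  stopifnot(length(expected) == k, all(expected >= 0))
  if (abs(sum(expected) - 1) > 1e-8) stop("expected proportions must sum to 1")
  if (any(expected == 0 & observed > 0))
    stop("zero expected proportion in a class with nonzero observed count; merge classes explicitly")
  keep <- expected > 0
  E <- expected[keep] * n
  stat <- sum((observed[keep] - E)^2 / E)
  df <- sum(keep) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

read_cross_table <- function(which = c("table2", "table3")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_f1_counts.csv"),
                      package = "drivesim", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Observed F1 counts from the sexing-cross experiments
#'
#' Packaged printed F1 class counts: `"table2"` (heterozygous gRNA mothers;
#' four marker classes, equal-assortment null) and `"table3"` (homozygous gRNA
#' mothers; two sex classes, 1:1 null), with the published chi-squared values
#' for comparison.
#'
#' @param which `"table2"` or `"table3"`.
#' @return A data.frame of line, class counts, and published statistic.
#' @export
cross_table_counts <- function(which = c("table2", "table3")) {
  read_cross_table(match.arg(which))
}

#' Recompute the published cross goodness-of-fit statistics
#'
#' Recomputes every chi-squared statistic from the packaged printed counts
#' under the stated nulls (heterozygous-mother table: equal assortment over
#' four marker classes, 3 df; homozygous-mother table: 1:1 sex ratio, 1 df)
#' and compares with the published values at their printed precision. Lines
#' with zero surviving offspring carry no statistic and are skipped.
#'
#' @return A data.frame with one row per cross line: `table`, `line`,
#'   `statistic`, `df`, `p_value`, `published`, `agrees`.
#' @export
reproduce_cross_tables <- function() {
  out <- list()
  for (tab in c("table2", "table3")) {
    d <- read_cross_table(tab)
    count_cols <- grep("^n_", names(d), value = TRUE)
    for (r in seq_len(nrow(d))) {
      obs <- as.numeric(d[r, count_cols])
      if (sum(obs) == 0) next
      g <- chisq_gof(obs)
      pub <- d$chisq_published[r]
      digits <- d$published_digits[r]
      out[[length(out) + 1L]] <- data.frame(
        table = tab, line = d$line[r], statistic = g$statistic, df = g$df,
        p_value = g$p_value, published = pub,
        agrees = round(g$statistic, digits) == pub,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Convert an observed inheritance fraction to a homing rate
#'
#' A drive allele inherited by a fraction `p` of offspring from a
#' heterozygous parent corresponds to a germline conversion (homing) rate
#' `h = 2p - 1`; Mendelian transmission (p = 0.5) gives h = 0. Fractions below
#' 0.5 (transmission deficit) are clamped to 0 and flagged.
#'
#' @param p_inherit Observed inheritance fraction(s) in \[0, 1\].
#' @return A data.frame with `p_inherit`, `homing_rate`, `clamped`.
#' @export
homing_rate_from_inheritance <- function(p_inherit) {
  stopifnot(all(p_inherit >= 0 & p_inherit <= 1))
  h <- 2 * p_inherit - 1
  clamped <- h < 0
  h[clamped] <- 0
  data.frame(p_inherit = p_inherit, homing_rate = h, clamped = clamped)
}

#' Maximum-likelihood penetrance estimate from observed F1 counts
#'
#' Under the cross's pre-viability class probabilities `q`, a lethal class
#' survives with relative weight `s = 1 - penetrance`; the observed fraction
#' of survivors falling in lethal classes identifies `s`. The closed-form MLE
#' is `s = qN * K / (qL * (N - K))` with `K` survivors in lethal classes out
#' of `N`, and `qL`, `qN` the pre-viability mass of lethal and non-lethal
#' classes. The standard error comes from the binomial variance of `K/N` by
#' the delta method.
#'
#' @param observed Named or ordered counts matching `enumerate_f1(cross)`
#'   classes.
#' @param cross A `cross_design`.
#' @return List with `penetrance`, `se`, `k_lethal`, `n`.
#' @export
estimate_penetrance <- function(observed, cross) {
  cls <- enumerate_f1(cross, penetrance = 0)   # pre-viability layout
  stopifnot(length(observed) == nrow(cls))
  if (!any(cls$lethal)) stop("cross has no lethal class; penetrance is not identifiable")
  N <- sum(observed)
  stopifnot(N > 0)
  K <- sum(observed[cls$lethal])
  qL <- sum(cls$pre_prob[cls$lethal])
  qN <- sum(cls$pre_prob[!cls$lethal])
  if (K == N) stop("all survivors fall in lethal classes; penetrance is not identifiable")
  p_hat <- K / N
  s_hat <- qN * K / (qL * (N - K))
  se <- (qN / qL) / (1 - p_hat)^2 * sqrt(p_hat * (1 - p_hat) / N)
  list(penetrance = min(max(1 - s_hat, 0), 1), se = se, k_lethal = K, n = N)
}
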