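# Broad-sense heritability and variance partitioning.
#
# H^2 = sigma^2_G / (sigma^2_G + sigma^2_E) from a one-way random-effects
# model with genotype (accession) as the random effect, fit by REML.
# Variance partitioning follows a fully crossed multifactorial ANOVA
# y ~ Env * Dev * Geno with sequential (type I) sums of squares in that term
# order; percent variance per term is SS_term / SS_total * 100.

#' Broad-sense heritability at one point
#'
#' Fits `value ~ 1 + (1 | genotype)` by REML ([lme4::lmer()]) and reports
#' `H^2 = sigma2_g / (sigma2_g + sigma2_e)`. Variance components are
#' truncated at zero. On designs where the mixed model fails to fit (for
#' example, zero residual variance), the balanced one-way ANOVA estimator
#' `sigma2_g = (MSB - MSW) / r` is used instead.
#'
#' @param values numeric trait values, one per plant.
#' @param genotype genotype (accession) label per plant.
#' @return a one-row `data.frame`: `sigma2_g`, `sigma2_e`, `h2`, `n`,
#'   `n_genotypes`.
#' @export
estimate_h2 <- function(values, genotype) {
  genotype <- as.factor(genotype)
  keep <- is.finite(values) & !is.na(genotype)
  values <- values[keep]; genotype <- droplevels(genotype[keep])
  if (nlevels(genotype) < 2L) stop("need at least 2 genotypes")
  if (!any(table(genotype) >= 2L)) stop("need replication within at least one genotype")
  comp <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(values ~ 1 + (1 | genotype),
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    c(g = vc$vcov[vc$grp == "genotype"], e = vc$vcov[vc$grp == "Residual"])
  }, error = function(e) {
    # balanced one-way ANOVA fallback (equals REML on balanced designs)
    r <- mean(table(genotype))
    msw <- mean(tapply(values, genotype, function(v) var1(v)))
    msb <- var1(tapply(values, genotype, mean)) * r
    c(g = (msb - msw) / r, e = msw)
  })
  s2g <- max(0, comp[["g"]]); s2e <- max(0, comp[["e"]])
  h2 <- if (s2g + s2e > 0) s2g / (s2g + s2e) else NA_real_
  data.frame(sigma2_g = s2g, sigma2_e = s2e, h2 = h2,
             n = length(values), n_genotypes = nlevels(genotype))
}

#' Heritability trajectory over developmental time
#'
#' Applies [estimate_h2()] at every grid point of a phenotype table.
#'
#' @param table phenotype table from [assemble_phenotype_table()].
#' @param trait trait to analyse (rows with `table$trait == trait`).
#' @return list with `trajectory` (`data.frame`: `rel_time`, `sigma2_g`,
#'   `sigma2_e`, `h2`, ...) and `summary` (`median`, `peak`, `peak_time`),
#'   computed over grid points with complete data.
#' @export
h2_trajectory <- function(table, trait = NULL) {
  if (!is.null(trait)) table <- table[table$trait == trait, , drop = FALSE]
  if (nrow(table) == 0L) stop("no rows for trait")
  gcols <- grep("^g\\d+$", names(table), value = TRUE)
  grid <- seq(0, 1, length.out = length(gcols))
  rows <- lapply(seq_along(gcols), function(i) {
    y <- table[[gcols[i]]]
    if (any(!is.finite(y))) return(NULL)
    cbind(rel_time = grid[i], estimate_h2(y, table$accession))
  })
  traj <- do.call(rbind, rows)
  if (is.null(traj)) stop("no grid point has complete data")
  list(trajectory = traj,
       summary = list(median = stats::median(traj$h2),
                      peak = max(traj$h2),
                      peak_time = traj$rel_time[which.max(traj$h2)]))
}

#' Multifactorial variance partitioning
#'
#' Fits `value ~ environment * development * genotype` with [stats::aov()]
#' (sequential sums of squares in that term order: main effects, then
#' two-way, then the three-way interaction) and reports each term's percent
#' of the total sum of squares with its F-test p-value.
#'
#' @param data `data.frame` with columns `value`, `environment`,
#'   `development` (categorical stage), `genotype`.
#' @return `data.frame`: `term`, `df`, `percent_variance`, `p_value`
#'   (residual row has `NA` p); percentages sum to 100.
#' @export
variance_partition <- function(data) {
  need <- c("value", "environment", "development", "genotype")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  d <- data.frame(value = data$value,
                  environment = as.factor(data$environment),
                  development = as.factor(data$development),
                  genotype = as.factor(data$genotype))
  for (f in need[-1]) if (nlevels(d[[f]]) < 2L) stop("factor ", f, " needs >= 2 levels")
  fit <- stats::aov(value ~ environment * development * genotype, data = d)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  if (any(tab$Df == 0))
    stop("aliased design; confounded terms: ",
         paste(terms[tab$Df == 0], collapse = ", "))
  ss <- tab[["Sum Sq"]]
  data.frame(term = terms, df = tab$Df,
             percent_variance = 100 * ss / sum(ss),
             p_value = tab[["Pr(>F)"]],
             stringsAsFactors = FALSE)
}

#' Per-grid-point correlation between two traits
#'
#' Pearson correlation across plants at each grid point, for example between
#' rosette area and circular area.
#'
#' @param table phenotype table holding both traits (long over `trait`).
#' @param trait_a,trait_b trait names.
#' @return list with `by_point` (`data.frame`: `rel_time`, `r`; `NA` where a
#'   trait has zero variance) and `range` (min/max of finite `r`).
#' @export
trait_correlation <- function(table, trait_a, trait_b) {
  a <- table[table$trait == trait_a, , drop = FALSE]
  b <- table[table$trait == trait_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) stop("traits not found in table")
  b <- b[match(a$plant_id, b$plant_id), , drop = FALSE]
  if (any(is.na(b$plant_id))) stop("traits measured on different plants")
  gcols <- grep("^g\\d+$", names(a), value = TRUE)
  grid <- seq(0, 1, length.out = length(gcols))
  r <- vapply(gcols, function(g) {
    x <- a[[g]]; y <- b[[g]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || var1(x[ok]) == 0 || var1(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  list(by_point = data.frame(rel_time = grid, r = unname(r)),
       range = range(r, na.rm = TRUE))
}
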