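# Statistical layer: two-sample Kolmogorov-Smirnov, one-way ANOVA, Spearman
# rank correlation, group summaries (mean +/- sample SD) and the disk-footprint
# mass model. Test engines are the base R implementations; this layer fixes
# the conventions (exact vs asymptotic p, tie handling, units) and the result
# container.

.stat_result <- function(test_name, statistic, p_value, n_per_group,
                         method_note, extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, n_per_group = n_per_group,
                   method_note = method_note), extra),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%s; n = %s)\n", x$test_name,
              x$statistic, x$p_value, x$method_note,
              paste(x$n_per_group, collapse = ", ")))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs. The p-value is
#' exact (permutation enumeration, tie-aware) when `n * m <= 10000`, else
#' asymptotic. p-value conventions differ across software, so p is reported
#' with a method note rather than treated as a portable quantity.
#'
#' @param a,b non-empty numeric samples.
#' @return a `stat_test_result` with `statistic` = D.
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  # D from a direct ECDF sweep over the pooled support (tie-safe)
  support <- sort(unique(c(a, b)))
  d_stat <- max(abs(ecdf(a)(support) - ecdf(b)(support)))
  exact <- length(a) * length(b) <= 10000
  kt <- suppressWarnings(ks.test(a, b, exact = exact))
  .stat_result("two-sample KS", d_stat, unname(kt$p.value),
               c(length(a), length(b)),
               if (exact) "exact (permutation enumeration)" else "asymptotic")
}

#' One-way ANOVA
#'
#' Classical equal-variance F test across groups.
#'
#' @param groups list of numeric samples, each with at least 2 observations.
#' @return a `stat_test_result` with `statistic` = F.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("every group needs at least 2 observations")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), times = n))
  within_var <- vapply(groups, var, numeric(1))
  means <- vapply(groups, mean, numeric(1))
  if (all(within_var == 0)) {
    if (diff(range(means)) == 0)
      return(.stat_result("one-way ANOVA", NaN, NA_real_, n,
                          "degenerate: zero within-group variance, equal means"))
    return(.stat_result("one-way ANOVA", Inf, 0, n,
                        "degenerate: zero within-group variance, unequal means"))
  }
  ot <- oneway.test(x ~ g, var.equal = TRUE)
  .stat_result("one-way ANOVA", unname(ot$statistic), unname(ot$p.value), n,
               "classical F test, equal variances")
}

#' Spearman rank correlation
#'
#' Average ranks on ties; exact p by enumeration for n <= 9 without ties,
#' t-approximation otherwise (the base R AS 89 / t conventions).
#'
#' @param x,y paired numeric samples of equal length >= 3.
#' @return a `stat_test_result` with `statistic` = rho.
#' @export
spearman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    return(.stat_result("Spearman rank correlation", NaN, NA_real_,
                        c(length(x), length(y)),
                        "degenerate: constant input, rho undefined"))
  exact <- length(x) <= 9L
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  .stat_result("Spearman rank correlation", unname(ct$estimate),
               unname(ct$p.value), c(length(x), length(y)),
               if (exact && !any(duplicated(x)) && !any(duplicated(y)))
                 "exact enumeration" else "t-approximation, average ranks on ties")
}

#' Group mean and sample SD of a per-PSD measurement
#'
#' Converts the 10^4-scaled table columns to base units (nm^2, nm, nm^3).
#' SD uses the n-1 denominator (the convention of the reference tables).
#'
#' @param table data.frame with columns `psd_id`, `group`, `area_1e4nm2`,
#'   `thickness_nm`, `volume_1e4nm3`.
#' @param field one of `"area"`, `"thickness"`, `"volume"`.
#' @param group group label present in `table$group`.
#' @return an object of class `group_summary`: `group`, `field`, `n`, `mean`,
#'   `sd` (NA with a flag when n = 1), `unit`.
#' @export
summarize_groups <- function(table, field = c("area", "thickness", "volume"),
                             group) {
  field <- match.arg(field)
  if (!group %in% table$group) stop("unknown group: ", group)
  rows <- table[table$group == group, , drop = FALSE]
  vals <- switch(field,
                 area = rows$area_1e4nm2 * 1e4,
                 thickness = rows$thickness_nm,
                 volume = rows$volume_1e4nm3 * 1e4)
  unit <- switch(field, area = "nm^2", thickness = "nm", volume = "nm^3")
  n <- length(vals)
  structure(list(group = group, field = field, n = n, mean = mean(vals),
                 sd = if (n > 1L) sd(vals) else NA_real_,
                 sd_defined = n > 1L, unit = unit),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s %s: %.3g +/- %.3g %s (n = %d)\n", x$group, x$field,
              x$mean, x$sd, x$unit, x$n))
  invisible(x)
}

#' Disk-footprint mass estimate of a module
#'
#' Treats the module as a disk of the given diameter carrying the PSD's areal
#' mass density: mass = density * pi * (size / 2)^2, in MDa, and the implied
#' protein count at a given mean protein mass (floored).
#'
#' @param size_nm module size (diameter), nm.
#' @param areal_density_kda_per_nm2 areal mass density, kDa/nm^2 (the
#'   published PSD estimate is ~10).
#' @param mean_protein_kda mean protein mass, kDa (default 100).
#' @return list with `mass_mda` and `protein_count`.
#' @export
estimate_module_mass <- function(size_nm, areal_density_kda_per_nm2 = 10,
                                 mean_protein_kda = 100) {
  if (size_nm <= 0 || areal_density_kda_per_nm2 <= 0 || mean_protein_kda <= 0)
    stop("all inputs must be positive")
  mass_kda <- areal_density_kda_per_nm2 * pi * (size_nm / 2)^2
  list(mass_mda = mass_kda / 1000,
       protein_count = floor(mass_kda / mean_protein_kda))
}
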