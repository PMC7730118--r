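#' Robust mean and standard deviation (Algorithm A)
#'
#' The iterative winsorised estimator used for interlaboratory consensus
#' values: initialise at the median and the scaled median absolute
#' deviation (factor 1.483), then repeatedly clamp values to
#' `x* +/- 1.5 s*`, take the mean and `1.134 x SD` of the clamped set,
#' until convergence. All laboratories contribute, but outliers are
#' down-weighted rather than excluded.
#'
#' @param values Numeric vector, one value per laboratory (>= 3).
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A list with `x_star`, `s_star`, `n_iterations`, `converged`,
#'   `method`.
#' @export
algorithm_A <- function(values, tol = 1e-9, max_iter = 100) {
  if (length(values) < 3) abort("need >= 3 values")
  if (anyNA(values)) abort("values must not contain NA")
  x_star <- median(values)
  s_star <- 1.483 * median(abs(values - x_star))
  if (s_star == 0) {
    if (all(values == values[1])) {
      return(list(x_star = x_star, s_star = 0, n_iterations = 0L,
                  converged = TRUE, method = "algorithm_A"))
    }
    warn("robust scale is 0 at initialisation; falling back to classical SD")
    s_star <- sd(values)
  }
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- pmin(pmax(values, x_star - 1.5 * s_star), x_star + 1.5 * s_star)
    x_new <- mean(w)
    s_new <- 1.134 * sd(w)
    dx <- abs(x_new - x_star) <= tol * max(abs(x_new), 1e-300)
    ds <- abs(s_new - s_star) <= tol * max(s_new, 1e-300)
    x_star <- x_new
    s_star <- s_new
    if (dx && ds) {
      converged <- TRUE
      break
    }
  }
  list(x_star = x_star, s_star = s_star, n_iterations = iter,
       converged = converged, method = "algorithm_A")
}

# Limit (eta) and adjustment (xi) factors of Algorithm S by degrees of
# freedom of the cell standard deviations, as tabulated in the standard.
ALGORITHM_S_FACTORS <- data.frame(
  nu = 1:10,
  eta = c(1.645, 1.517, 1.444, 1.395, 1.359, 1.332, 1.310, 1.292, 1.277,
          1.264),
  xi = c(1.097, 1.054, 1.039, 1.032, 1.027, 1.024, 1.021, 1.019, 1.018,
         1.017)
)

#' Robust pooled within-laboratory standard deviation (Algorithm S)
#'
#' Pools cell (within-lab) standard deviations robustly: SDs above
#' `eta x s*` are capped at that limit and the root mean square of the
#' capped values, times the adjustment factor `xi`, becomes the new
#' `s*`, iterated to convergence. `eta` and `xi` depend on the degrees
#' of freedom `nu = replicates - 1` of each cell SD.
#'
#' @param cell_sds One standard deviation per laboratory (>= 3).
#' @param nu Degrees of freedom of each cell SD (replicates - 1).
#' @param tol,max_iter Convergence control.
#' @return The robust pooled SD (0 when all cell SDs are 0).
#' @export
algorithm_S <- function(cell_sds, nu, tol = 1e-9, max_iter = 100) {
  if (length(cell_sds) < 3) abort("need >= 3 cell SDs")
  if (nu < 1) abort("nu must be >= 1")
  if (any(cell_sds < 0)) abort("cell SDs must be >= 0")
  if (all(cell_sds == 0)) return(0)
  f <- ALGORITHM_S_FACTORS[pmin(as.integer(nu), 10L), ]
  if (nu > 10) {
    warn("Algorithm S factors tabulated up to nu = 10; using nu = 10 values")
  }
  p <- length(cell_sds)
  s_star <- median(cell_sds)
  if (s_star == 0) s_star <- sqrt(mean(cell_sds^2))
  for (iter in seq_len(max_iter)) {
    psi <- f$eta * s_star
    w <- pmin(cell_sds, psi)
    s_new <- f$xi * sqrt(sum(w^2) / p)
    if (abs(s_new - s_star) <= tol * max(s_new, 1e-300)) {
      s_star <- s_new
      break
    }
    s_star <- s_new
  }
  s_star
}

validate_ilc_data <- function(data, value, lab) {
  data <- as_tibble(data)
  if (!all(c(lab, value) %in% names(data))) {
    abort(sprintf("data must have columns '%s' and '%s'", lab, value))
  }
  data <- dplyr::filter(data, !is.na(.data[[value]]))
  labs <- unique(data[[lab]])
  if (length(labs) < 2) abort("need >= 2 laboratories")
  data
}

cell_stats <- function(data, value, lab) {
  dplyr::summarise(
    dplyr::group_by(data, lab = .data[[lab]]),
    cell_mean = mean(.data[[value]]),
    cell_sd = sd(.data[[value]]),
    n = dplyr::n(),
    .groups = "drop"
  )
}

new_precision_estimates <- function(method, x_pt, u_xpt, s_R, s_r, p, n_bar,
                                    flags = tibble(lab = character(),
                                                   test = character(),
                                                   level = character())) {
  rsd <- function(s) if (is.na(x_pt) || x_pt == 0) NA_real_ else 100 * s / x_pt
  structure(
    list(
      method = method, x_pt = x_pt, u_xpt = u_xpt,
      s_R = s_R, s_r = s_r,
      rsd_R_pct = rsd(s_R), rsd_r_pct = rsd(s_r),
      n_labs = p, mean_replicates = n_bar,
      flags = flags
    ),
    class = "precision_estimates"
  )
}

#' @export
print.precision_estimates <- function(x, ...) {
  cat(sprintf(
    paste0("<precision_estimates> (%s, p = %d labs, n ~ %.3g replicates)\n",
           "  X_pt = %.5g (U = %.3g)\n",
           "  reproducibility R = %.4g (RSD_R %.3g%%), repeatability r = %.4g (RSD_r %.3g%%)\n"),
    x$method, x$n_labs, x$mean_replicates, x$x_pt, x$u_xpt,
    x$s_R, x$rsd_R_pct, x$s_r, x$rsd_r_pct
  ))
  if (nrow(x$flags)) {
    cat("  flagged:", paste(sprintf("%s (%s, %s)", x$flags$lab, x$flags$test,
                                    x$flags$level), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Robust interlaboratory precision (consensus, R, r)
#'
#' Computes the consensus value and the reproducibility and repeatability
#' standard deviations of a lab x replicate dataset with the robust
#' estimators: Algorithm A on the cell means gives the consensus `X_pt`
#' and the between-cell scale `s_d*`; Algorithm S on the cell SDs gives
#' the repeatability `s_r`; the reproducibility is
#' `s_R = sqrt(s_d*^2 + s_r^2 (1 - 1/n_bar))` (floored at `s_r`), and the
#' consensus uncertainty is twice its standard error,
#' `U = 2 s_d*/sqrt(p)`.
#'
#' @param data Long data frame with one row per replicate.
#' @param value,lab Column names of the measured value and the laboratory
#'   identifier.
#' @return A `precision_estimates`.
#' @export
robust_precision <- function(data, value = "value", lab = "lab") {
  data <- validate_ilc_data(data, value, lab)
  cells <- cell_stats(data, value, lab)
  p <- nrow(cells)
  n_bar <- mean(cells$n)
  a <- algorithm_A(cells$cell_mean)
  sds <- cells$cell_sd[!is.na(cells$cell_sd)]
  s_r <- if (length(sds) >= 3) {
    algorithm_S(sds, nu = max(1L, as.integer(round(n_bar - 1))))
  } else if (length(sds) > 0) sqrt(mean(sds^2)) else 0
  s_R <- max(sqrt(a$s_star^2 + s_r^2 * (1 - 1 / n_bar)), s_r)
  new_precision_estimates(
    "iso5725_5_robust",
    x_pt = a$x_star,
    u_xpt = 2 * a$s_star / sqrt(p),
    s_R = s_R, s_r = s_r, p = p, n_bar = n_bar
  )
}

# critical value of Cochran's variance-homogeneity statistic
# (max s_i^2 / sum s_i^2) via the F-distribution closed form
cochran_critical <- function(alpha, p, nu) {
  1 / (1 + (p - 1) / qf(alpha / p, nu, (p - 1) * nu, lower.tail = FALSE))
}

# critical value of the single-Grubbs statistic max|x - xbar|/s
grubbs_critical <- function(alpha, n) {
  t <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Classical interlaboratory precision with outlier screening
#'
#' The outlier-exclusion route: cell variances are screened with
#' Cochran's test and cell means with Grubbs' test, iteratively; cells
#' significant at `alpha_outlier` are removed as outliers, those between
#' `alpha_straggler` and `alpha_outlier` are flagged as stragglers but
#' retained. The retained cells are then decomposed by one-way ANOVA:
#' `s_r^2` is the pooled within-cell variance,
#' `s_L^2 = max(0, s_d^2 - s_r^2/n_bar)` with `s_d` the SD of cell means,
#' and `s_R^2 = s_L^2 + s_r^2`. Critical values are computed from the F
#' and t distributions rather than hard-coded tables.
#'
#' @inheritParams robust_precision
#' @param alpha_straggler,alpha_outlier Significance levels for flagging
#'   (default 5%) and exclusion (default 1%).
#' @param max_iter Cap on screening rounds.
#' @return A `precision_estimates` with a `flags` table naming outlier and
#'   straggler laboratories.
#' @export
classical_precision <- function(data, value = "value", lab = "lab",
                                alpha_straggler = 0.05, alpha_outlier = 0.01,
                                max_iter = 10) {
  data <- validate_ilc_data(data, value, lab)
  cells <- cell_stats(data, value, lab)
  flags <- tibble(lab = character(), test = character(), level = character())
  note_flag <- function(lab_id, test, level) {
    flags <<- dplyr::bind_rows(flags, tibble(lab = as.character(lab_id),
                                             test = test, level = level))
  }
  for (i in seq_len(max_iter)) {
    p <- nrow(cells)
    if (p < 3) abort("fewer than 3 laboratories remain after outlier removal")
    # never reduce the design below 3 laboratories: at p = 3 suspects are
    # flagged as stragglers but retained
    can_remove <- p > 3
    removed <- FALSE
    nu <- round(mean(cells$n)) - 1
    sds_ok <- !is.na(cells$cell_sd)
    if (nu >= 1 && sum(sds_ok) >= 3 && any(cells$cell_sd[sds_ok] > 0)) {
      v <- cells$cell_sd[sds_ok]^2
      C <- max(v) / sum(v)
      i_max <- which(sds_ok)[which.max(v)]
      if (can_remove && C > cochran_critical(alpha_outlier, sum(sds_ok), nu)) {
        note_flag(cells$lab[i_max], "cochran", "outlier")
        cells <- cells[-i_max, ]
        removed <- TRUE
      } else if (C > cochran_critical(alpha_straggler, sum(sds_ok), nu)) {
        if (!any(flags$lab == as.character(cells$lab[i_max]) &
                   flags$test == "cochran")) {
          note_flag(cells$lab[i_max], "cochran", "straggler")
        }
      }
    }
    if (!removed && nrow(cells) >= 3) {
      m <- cells$cell_mean
      G <- max(abs(m - mean(m))) / sd(m)
      i_max <- which.max(abs(m - mean(m)))
      if (can_remove && is.finite(G) &&
            G > grubbs_critical(alpha_outlier, length(m))) {
        note_flag(cells$lab[i_max], "grubbs", "outlier")
        cells <- cells[-i_max, ]
        removed <- TRUE
      } else if (is.finite(G) &&
                   G > grubbs_critical(alpha_straggler, length(m))) {
        if (!any(flags$lab == as.character(cells$lab[i_max]) &
                   flags$test == "grubbs")) {
          note_flag(cells$lab[i_max], "grubbs", "straggler")
        }
      }
    }
    if (!removed) break
  }
  p <- nrow(cells)
  n_bar <- mean(cells$n)
  x_pt <- mean(cells$cell_mean)
  nu_cells <- cells$n - 1
  s_r2 <- if (sum(nu_cells) > 0) {
    sum(nu_cells * cells$cell_sd^2, na.rm = TRUE) / sum(nu_cells)
  } else 0
  s_d2 <- var(cells$cell_mean)
  s_L2 <- max(0, s_d2 - s_r2 / n_bar)
  s_r <- sqrt(s_r2)
  s_R <- max(sqrt(s_L2 + s_r2), s_r)
  new_precision_estimates(
    "iso5725_2_classical",
    x_pt = x_pt,
    u_xpt = 2 * sqrt(s_d2 / p),
    s_R = s_R, s_r = s_r, p = p, n_bar = n_bar,
    flags = flags
  )
}

#' Evaluate every measurand of an interlaboratory dataset
#'
#' Applies [robust_precision()] (and optionally [classical_precision()])
#' per measurand of a long lab x replicate table, producing the shape of
#' a collaborative-trial results table: one row per measurand and method
#' with `X_pt`, `U`, `R`, `r`, `RSD_R`, `RSD_r`.
#'
#' @param data Long data frame with columns for measurand, lab and value.
#' @param measurand,value,lab Column names.
#' @param methods Which evaluations to run.
#' @return A tibble, one row per measurand x method.
#' @export
ilc_precision <- function(data, measurand = "measurand", value = "value",
                          lab = "lab",
                          methods = c("robust", "classical")) {
  methods <- match.arg(methods, several.ok = TRUE)
  data <- as_tibble(data)
  if (!measurand %in% names(data)) {
    abort(sprintf("data must have a '%s' column", measurand))
  }
  groups <- split(data, data[[measurand]])
  # preserve first-appearance order of measurands
  groups <- groups[unique(as.character(data[[measurand]]))]
  purrr::imap(groups, function(g, m) {
    # measurands with no evaluable data (e.g. no dilution chain, so no
    # sample-referenced concentrations) keep their row, with NA statistics
    ok <- !is.na(g[[value]])
    if (dplyr::n_distinct(g[[lab]][ok]) < 2) {
      return(purrr::map(intersect(methods, c("robust", "classical")),
                        function(meth) {
        tibble(measurand = m,
               method = if (meth == "robust") "iso5725_5_robust"
                        else "iso5725_2_classical",
               x_pt = NA_real_, u_xpt = NA_real_, s_R = NA_real_,
               s_r = NA_real_, rsd_R_pct = NA_real_, rsd_r_pct = NA_real_,
               n_labs = 0L, mean_replicates = NA_real_,
               n_outliers = 0L, n_stragglers = 0L)
      }) |> dplyr::bind_rows())
    }
    rows <- list()
    if ("robust" %in% methods) {
      rows <- c(rows, list(dplyr::mutate(
        generics::glance(robust_precision(g, value = value, lab = lab)),
        measurand = m, .before = 1)))
    }
    if ("classical" %in% methods) {
      rows <- c(rows, list(dplyr::mutate(
        generics::glance(classical_precision(g, value = value, lab = lab)),
        measurand = m, .before = 1)))
    }
    dplyr::bind_rows(rows)
  }) |>
    dplyr::bind_rows()
}

# half unit-in-the-last-place of a printed number given as a string
printed_half_ulp <- function(s) {
  s <- trimws(s)
  mant <- sub("[eE].*$", "", s)
  expo <- if (grepl("[eE]", s)) {
    as.numeric(sub("^.*[eE]", "", s))
  } else 0
  dec <- if (grepl("\\.", mant)) nchar(sub("^[^.]*\\.", "", mant)) else 0
  0.5 * 10^(expo - dec)
}

#' Check a printed precision triple for internal consistency
#'
#' Published collaborative-trial tables print the consensus `X_pt`, a
#' precision SD `s` (reproducibility or repeatability) and the
#' corresponding RSD in percent, each rounded to its displayed digits.
#' The identity `RSD = 100 s / X_pt` can only be expected to hold within
#' the rounding of the printed values; this check propagates half an ULP
#' (unit in the last place) of each printed number and tests whether the
#' printed RSD interval overlaps the feasible interval.
#'
#' @param x_pt,s,rsd_pct Printed values, as the character strings shown in
#'   the table (so the printed precision is known).
#' @return `TRUE` when consistent. Vectorised.
#' @examples
#' check_precision_consistency("158", "12.3", "7.8")
#' @export
check_precision_consistency <- function(x_pt, s, rsd_pct) {
  mapply(function(xs, ss, rs) {
    x <- as.numeric(xs); sv <- as.numeric(ss); r <- as.numeric(rs)
    hx <- printed_half_ulp(xs); hs <- printed_half_ulp(ss)
    hr <- printed_half_ulp(rs)
    lo <- 100 * (sv - hs) / (x + hx)
    hi <- 100 * (sv + hs) / (x - hx)
    (r + hr) >= lo && (r - hr) <= hi
  }, x_pt, s, rsd_pct, USE.NAMES = FALSE)
}
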