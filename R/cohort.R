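#' Homeostasis Model Assessment of Insulin Resistance (HOMA-IR)
#'
#' HOMA-IR = fasting glucose (mmol/l) x fasting insulin (mU/l) / 22.5.
#'
#' @param glucose fasting plasma glucose, mmol/l; strictly positive.
#' @param insulin fasting serum insulin, mU/l; strictly positive.
#' @return numeric vector of HOMA-IR values (pure number).
#' @examples
#' homa_ir(4.5, 5)   # 1
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(!is.finite(glucose)) || any(glucose <= 0))
    stop("glucose must be strictly positive")
  if (any(!is.finite(insulin)) || any(insulin <= 0))
    stop("insulin must be strictly positive")
  glucose * insulin / 22.5
}

#' Select extreme HOMA-IR groups within a BMI window
#'
#' Reconstructs an extreme-group design: within the open BMI window
#' `bmi_min < BMI < bmi_max`, the `n_per_group` subjects with the lowest
#' HOMA-IR form the low (insulin-sensitive) group and the `n_per_group`
#' highest form the high (insulin-resistant) group. A deterministic greedy
#' pass then swaps group members for alternative candidates — restricted to
#' the bottom/top thirds of the in-window HOMA-IR distribution — to minimise
#' the summed standardised group differences in the matching variables
#' (age, sex and BMI by default). When `"sex"` is among `match_vars` the two
#' groups are additionally required to end with identical sex counts.
#'
#' Both BMI bounds are strict inequalities, so `bmi_max = 25` excludes
#' BMI >= 25 and `bmi_min = 25` requires BMI > 25.
#'
#' @param clinical data.frame as returned by [read_clinical()].
#' @param bmi_min,bmi_max open BMI window bounds (default unbounded).
#' @param n_per_group group size (default 10).
#' @param match_vars variables to balance; subset of
#'   `c("age", "sex", "bmi")` plus any numeric clinical column.
#' @return object of class `group_selection`: list with `low_group`,
#'   `high_group` (subject ids), and a `criteria` record.
#' @export
select_extreme_groups <- function(clinical, bmi_min = -Inf, bmi_max = Inf,
                                  n_per_group = 10,
                                  match_vars = c("age", "sex", "bmi")) {
  stopifnot(is.data.frame(clinical), n_per_group >= 1)
  df <- clinical[order(clinical$id), , drop = FALSE]  # row-order invariance
  if (is.null(df$homa_ir)) df$homa_ir <- homa_ir(df$glucose, df$insulin)
  df <- df[df$bmi > bmi_min & df$bmi < bmi_max, , drop = FALSE]
  if (nrow(df) < 2 * n_per_group)
    stop("BMI window holds ", nrow(df), " subjects; need at least ",
         2 * n_per_group)
  ord <- order(df$homa_ir, df$id)
  df <- df[ord, , drop = FALSE]
  n <- nrow(df)
  third <- max(n_per_group, floor(n / 3))
  low_pool <- seq_len(third)
  high_pool <- seq.int(n - third + 1L, n)

  num_vars <- setdiff(match_vars, "sex")
  bad <- setdiff(num_vars, colnames(df))
  if (length(bad)) stop("unknown match variable(s): ", paste(bad, collapse = ", "))
  scales <- vapply(num_vars, function(v) {
    s <- stats::sd(df[[v]]); if (!is.finite(s) || s == 0) 1 else s
  }, numeric(1L))
  match_sex <- "sex" %in% match_vars
  sex01 <- if (match_sex) as.integer(factor(df$sex)) else NULL

  objective <- function(low, high) {
    obj <- 0
    for (v in num_vars)
      obj <- obj + abs(mean(df[[v]][low]) - mean(df[[v]][high])) / scales[[v]]
    if (match_sex)
      obj <- obj + 1e6 * sum(abs(tabulate(sex01[low], nbins = max(sex01)) -
                                 tabulate(sex01[high], nbins = max(sex01))))
    obj
  }

  low <- seq_len(n_per_group)
  high <- seq.int(n - n_per_group + 1L, n)
  obj <- objective(low, high)
  repeat {
    best <- NULL
    for (side in c("low", "high")) {
      grp <- if (side == "low") low else high
      pool <- setdiff(if (side == "low") low_pool else high_pool,
                      c(low, high))
      for (out_i in grp) for (in_i in pool) {
        cand <- sort(c(setdiff(grp, out_i), in_i))
        o <- if (side == "low") objective(cand, high) else objective(low, cand)
        if (o < obj - 1e-12 && (is.null(best) || o < best$obj)) {
          best <- list(obj = o, side = side, grp = cand)
        }
      }
    }
    if (is.null(best)) break
    obj <- best$obj
    if (best$side == "low") low <- best$grp else high <- best$grp
  }
  if (match_sex &&
      !identical(tabulate(sex01[low], nbins = max(sex01)),
                 tabulate(sex01[high], nbins = max(sex01))))
    stop("exact sex matching is unattainable within the candidate pools")

  structure(list(
    low_group = df$id[low],
    high_group = df$id[high],
    criteria = list(bmi_min = bmi_min, bmi_max = bmi_max,
                    n_per_group = n_per_group, match_vars = match_vars,
                    objective = obj,
                    homa_ir_means = c(low = mean(df$homa_ir[low]),
                                      high = mean(df$homa_ir[high])))),
    class = "group_selection")
}

#' @export
print.group_selection <- function(x, ...) {
  cat("Extreme HOMA-IR group selection\n")
  cat("  low  (n=", length(x$low_group), "): ",
      paste(x$low_group, collapse = ", "), "\n", sep = "")
  cat("  high (n=", length(x$high_group), "): ",
      paste(x$high_group, collapse = ", "), "\n", sep = "")
  m <- x$criteria$homa_ir_means
  cat(sprintf("  HOMA-IR means: low %.3g, high %.3g (ratio %.3g)\n",
              m["low"], m["high"], m["high"] / m["low"]))
  invisible(x)
}
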