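#' @title Between- and within-tooth color-difference analysis
#' @description Reproduces the result structure of an anterior-tooth shade
#'   study: per-third and overall differences between contralateral teeth
#'   (same tooth type across the midline: UCI1-UCI2, ULI1-ULI2) and adjacent
#'   teeth (central vs lateral on one side: UCI1-ULI1, UCI2-ULI2), and
#'   differences between the thirds of a single tooth, each judged against
#'   the dental PT/AT thresholds.
#' @name analysis
NULL

.delta_e_fun <- function(formula, params) {
  formula <- match.arg(formula, c("CIELAB", "CIEDE2000"))
  if (formula == "CIELAB") {
    function(x, y) delta_e_ab(x, y)$value
  } else {
    function(x, y) ciede2000(x, y, params)$value
  }
}

#' Per-third color difference between two teeth
#'
#' Delta E between the two teeth's mean Lab of each matching third —
#' a difference of means, not a mean of per-pixel differences.
#'
#' @param a,b [tooth_color_profile()]s.
#' @param formula `"CIELAB"` or `"CIEDE2000"`.
#' @param params [de2000_params()] used when `formula = "CIEDE2000"`.
#' @return Named numeric vector `(cervical, middle, incisal)`.
#' @export
per_third_difference <- function(a, b, formula = c("CIELAB", "CIEDE2000"),
                                 params = de2000_params()) {
  formula <- match.arg(formula)
  de <- .delta_e_fun(formula, params)
  vapply(c(cervical = "cervical", middle = "middle", incisal = "incisal"),
         function(th) de(third_lab(a, th), third_lab(b, th)), numeric(1))
}

#' Overall color difference between two teeth
#'
#' Unweighted arithmetic mean of the three per-third Delta E values. This
#' mean-over-thirds rule is the operative definition of the "overall"
#' difference between two teeth: applied to the per-third mean colors it
#' reproduces the published whole-tooth values exactly.
#'
#' @inheritParams per_third_difference
#' @return A single Delta E value.
#' @export
overall_difference <- function(a, b, formula = c("CIELAB", "CIEDE2000"),
                               params = de2000_params()) {
  mean(per_third_difference(a, b, formula, params))
}

#' Color differences between thirds of one tooth
#'
#' Delta E between the mean Lab of cervical and middle (`d_CM`), cervical
#' and incisal (`d_CI`), and middle and incisal (`d_MI`) thirds.
#'
#' @param p A [tooth_color_profile()].
#' @inheritParams per_third_difference
#' @return Named numeric vector `(d_CM, d_CI, d_MI)`.
#' @export
within_tooth_differences <- function(p, formula = c("CIELAB", "CIEDE2000"),
                                     params = de2000_params()) {
  formula <- match.arg(formula)
  de <- .delta_e_fun(formula, params)
  c(d_CM = de(third_lab(p, "cervical"), third_lab(p, "middle")),
    d_CI = de(third_lab(p, "cervical"), third_lab(p, "incisal")),
    d_MI = de(third_lab(p, "middle"), third_lab(p, "incisal")))
}

# Pair typing for the four maxillary incisors.
.pair_type <- function(id1, id2) {
  key <- paste(sort(c(id1, id2)), collapse = "-")
  contral <- c("UCI1-UCI2", "ULI1-ULI2")
  adjac <- c("UCI1-ULI1", "UCI2-ULI2")
  if (key %in% contral) "contralateral" else if (key %in% adjac) "adjacent"
  else "other"
}

#' Full shade-analysis report
#'
#' Materializes the study's result tables from a set of per-tooth profiles:
#' (i) the per-third mean/SD table, (ii) pairwise comparisons (per-third and
#' overall Delta E, both formulas, with PT/AT verdicts), and (iii)
#' within-tooth third comparisons for both formulas. With the four incisor
#' labels present, pairs are restricted to the contralateral and adjacent
#' ones; for free labels every unordered pair is reported as type `"other"`.
#' Ordering is deterministic (input order of profiles; cervical, middle,
#' incisal; CIELAB before CIEDE2000).
#'
#' @param profiles List of [tooth_color_profile()]s with distinct ids.
#' @param thresholds A [delta_e_thresholds()].
#' @param params A [de2000_params()].
#' @return Object of class `tooth_color_report`: data frames `profiles`,
#'   `pairs`, `within`.
#' @export
tooth_color_report <- function(profiles, thresholds = delta_e_thresholds(),
                               params = de2000_params()) {
  if (inherits(profiles, "tooth_color_profile")) profiles <- list(profiles)
  ids <- unname(vapply(profiles, `[[`, character(1), "tooth_id"))
  if (anyDuplicated(ids))
    stop("duplicate tooth_id in profiles: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(profiles) <- ids

  canonical <- all(c("UCI1", "UCI2", "ULI1", "ULI2") %in% ids) ||
    all(ids %in% c("UCI1", "UCI2", "ULI1", "ULI2"))
  pair_idx <- if (length(ids) >= 2L) utils::combn(ids, 2L, simplify = FALSE)
  else list()
  if (canonical)
    pair_idx <- Filter(function(p) .pair_type(p[1L], p[2L]) != "other",
                       pair_idx)

  pair_rows <- list()
  for (p in pair_idx) {
    for (formula in c("CIELAB", "CIEDE2000")) {
      thirds <- per_third_difference(profiles[[p[1L]]], profiles[[p[2L]]],
                                     formula, params)
      ov <- mean(thirds)
      vals <- c(thirds, overall = ov)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        tooth_1 = p[1L], tooth_2 = p[2L],
        type = .pair_type(p[1L], p[2L]),
        formula = formula,
        comparison = names(vals),
        delta_e = unname(vals),
        verdict = unname(vapply(vals, classify_delta_e, character(1),
                                thresholds = thresholds, formula = formula))
      )
    }
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(tooth_1 = character(), tooth_2 = character(),
               type = character(), formula = character(),
               comparison = character(), delta_e = numeric(),
               verdict = character())

  within_rows <- list()
  for (id in ids) {
    for (formula in c("CIELAB", "CIEDE2000")) {
      w <- within_tooth_differences(profiles[[id]], formula, params)
      within_rows[[length(within_rows) + 1L]] <- data.frame(
        tooth_id = id, formula = formula,
        comparison = c("cervical-middle", "cervical-incisal",
                       "middle-incisal"),
        delta_e = unname(w),
        verdict = unname(vapply(w, classify_delta_e, character(1),
                                thresholds = thresholds, formula = formula))
      )
    }
  }
  within <- do.call(rbind, within_rows)
  rownames(pairs) <- rownames(within) <- NULL

  structure(list(profiles = profiles_to_df(profiles), pairs = pairs,
                 within = within, thresholds = thresholds, params = params),
            class = "tooth_color_report")
}

#' @export
print.tooth_color_report <- function(x, digits = 2, ...) {
  cat("Tooth shade analysis report\n")
  cat("===========================\n\n")
  cat("Per-third mean CIELAB:\n")
  pf <- x$profiles
  pf[c("L", "a", "b")] <- lapply(pf[c("L", "a", "b")], round_half_up, digits)
  print(pf[c("tooth_id", "third", "L", "a", "b")], row.names = FALSE)
  if (nrow(x$pairs)) {
    cat("\nBetween-teeth differences (dE, verdict vs PT/AT):\n")
    pr <- x$pairs
    pr$delta_e <- round_half_up(pr$delta_e, digits)
    print(pr, row.names = FALSE)
  }
  if (nrow(x$within)) {
    cat("\nWithin-tooth differences between thirds:\n")
    wi <- x$within
    wi$delta_e <- round_half_up(wi$delta_e, digits)
    print(wi, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.tooth_color_report <- function(x, which = c("pairs", "within"), ...) {
  which <- match.arg(which)
  df <- if (which == "pairs") {
    d <- x$pairs[x$pairs$comparison == "overall", ]
    if (!nrow(d)) stop("no pairwise comparisons in this report", call. = FALSE)
    d$label <- paste(d$tooth_1, d$tooth_2, sep = "-")
    d
  } else {
    d <- x$within
    d$label <- paste(d$tooth_id, d$comparison)
    d
  }
  ab <- df[df$formula == "CIELAB", ]
  e00 <- df[df$formula == "CIEDE2000", ]
  hs <- rbind(ab$delta_e, e00$delta_e[match(ab$label, e00$label)])
  bp <- graphics::barplot(hs, beside = TRUE, names.arg = ab$label,
                          las = 2, ylab = expression(Delta * E),
                          legend.text = c(expression(Delta * E["ab"]^"*"),
                                          expression(Delta * E["00"])),
                          args.legend = list(x = "topleft", bty = "n"), ...)
  graphics::abline(h = c(x$thresholds$PT_ab, x$thresholds$AT_ab),
                   lty = 2, col = "grey40")
  graphics::abline(h = c(x$thresholds$PT_00, x$thresholds$AT_00),
                   lty = 3, col = "grey60")
  invisible(bp)
}

#' Read analysis configuration from YAML
#'
#' Recognized top-level keys (all optional): `thresholds` (`PT_ab`, `PT_00`,
#' `AT_ab`, `AT_00`), `de2000` (`kL`, `kC`, `kH`), `integration_range`
#' (`lo_nm`, `hi_nm`), `mask` (`min_L`, `max_ab_radius`), `seed`.
#' Missing keys fall back to package defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return List with `thresholds`, `params`, `integration_range`, `mask`,
#'   `seed`.
#' @export
shade_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  thr <- do.call(delta_e_thresholds, cfg$thresholds %||% list())
  par <- do.call(de2000_params, cfg$de2000 %||% list())
  ir <- utils::modifyList(list(lo_nm = 400, hi_nm = 780),
                          cfg$integration_range %||% list())
  mk <- utils::modifyList(list(min_L = 45, max_ab_radius = 40),
                          cfg$mask %||% list())
  list(thresholds = thr, params = par, integration_range = ir, mask = mk,
       seed = cfg$seed %||% NULL)
}
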