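# Congener mole-percent profiles and time courses: the unit of all
# dechlorination metrics.

#' Congener mole-percent profile at one timepoint
#'
#' Entries must be non-negative and sum to 100 within +/- 0.5 (GC-MS
#' mole-percent tables routinely carry rounding drift); inside that band the
#' profile is renormalized to exactly 100, outside it is an error.
#' Congeners not listed are treated as exact zeros (the "not detected"
#' semantics of congener analysis), not as missing.
#'
#' @param congeners vector of congener identifiers (see [parse_congener()]).
#' @param mole_percent numeric vector of mole percentages, same length.
#' @param time sampling time in days.
#' @param system system/treatment label, e.g. `"M-HM"`.
#' @return Object of class `"congener_profile"`: list with `system`, `time`
#'   and `mole_percent` (named by BZ number, summing to exactly 100).
#' @examples
#' p <- congener_profile(c("PCB47", "PCB153"), c(20, 80))
#' average_chlorine(p)
#' @export
congener_profile <- function(congeners, mole_percent, time = 0, system = "system") {
  bz <- parse_congener(congeners)
  if (anyDuplicated(bz)) stop("duplicated congeners in profile", call. = FALSE)
  if (length(bz) == 0L) stop("empty congener profile", call. = FALSE)
  mole_percent <- as.numeric(mole_percent)
  if (length(mole_percent) != length(bz)) {
    stop("congeners and mole_percent lengths differ", call. = FALSE)
  }
  if (anyNA(mole_percent) || any(mole_percent < 0)) {
    stop("mole percentages must be non-negative", call. = FALSE)
  }
  total <- sum(mole_percent)
  if (abs(total - 100) > 0.5) {
    stop(sprintf("profile mole percentages sum to %.3f; must be within 100 +/- 0.5",
                 total), call. = FALSE)
  }
  mp <- mole_percent * (100 / total)
  names(mp) <- as.character(bz)
  structure(list(system = system, time = as.numeric(time), mole_percent = mp),
            class = "congener_profile")
}

#' @export
print.congener_profile <- function(x, ...) {
  cat(sprintf("<congener_profile> %s, day %g: %d congeners, avg Cl %.3f\n",
              x$system, x$time, length(x$mole_percent), average_chlorine(x)))
  invisible(x)
}

#' Average number of chlorines per biphenyl
#'
#' The mole-fraction-weighted mean chlorine count of the mixture; its decline
#' over time quantifies dechlorination extent.
#'
#' @param p a `"congener_profile"`.
#' @return Average chlorines per biphenyl, in `[0, 10]`.
#' @export
average_chlorine <- function(p) {
  stopifnot(inherits(p, "congener_profile"))
  bz <- as.integer(names(p$mole_percent))
  sum(p$mole_percent / 100 * congener_ncl(bz))
}

#' Homolog (chlorination-degree) distribution of a profile
#'
#' @param p a `"congener_profile"`.
#' @return Named numeric vector of mole percentages for 0-10 chlorines
#'   (names `"0"`..`"10"`), summing to 100.
#' @export
homolog_distribution <- function(p) {
  stopifnot(inherits(p, "congener_profile"))
  bz <- as.integer(names(p$mole_percent))
  ncl <- congener_ncl(bz)
  out <- numeric(11)
  names(out) <- as.character(0:10)
  agg <- tapply(p$mole_percent, ncl, sum)
  out[names(agg)] <- agg
  out
}

#' Dechlorination time course for one culture system
#'
#' @param profiles list of [congener_profile()] objects with strictly
#'   increasing times (the system label of the first profile is used).
#' @param mass_conc_mg_l nominal mixture mass concentration in mg/L
#'   (25 mg/L for an Aroclor 1260 spike at the study's dose).
#' @return Object of class `"dechlor_timecourse"`.
#' @export
dechlor_timecourse <- function(profiles, mass_conc_mg_l = 25) {
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, logical(1), "congener_profile")))
  times <- vapply(profiles, `[[`, numeric(1), "time")
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(diff(times) <= 0)) stop("profile times must be strictly increasing",
                                  call. = FALSE)
  if (mass_conc_mg_l <= 0) stop("mass concentration must be positive", call. = FALSE)
  structure(list(system = profiles[[1]]$system, mass_conc_mg_l = mass_conc_mg_l,
                 times = times, profiles = profiles),
            class = "dechlor_timecourse")
}

#' @export
print.dechlor_timecourse <- function(x, ...) {
  cat(sprintf("<dechlor_timecourse> %s: %d profiles, days %s; %g mg/L\n",
              x$system, length(x$profiles),
              paste(x$times, collapse = ", "), x$mass_conc_mg_l))
  invisible(x)
}

#' Extract the profile at (or before) a sampling time
#'
#' @param tc a `"dechlor_timecourse"`.
#' @param at day; with `exact = TRUE` (default) the time must have been
#'   sampled, otherwise the profile at the greatest sampled time `<= at` is
#'   returned.
#' @param exact require an exact time match.
#' @return A `"congener_profile"`.
#' @export
profile_at <- function(tc, at, exact = TRUE) {
  stopifnot(inherits(tc, "dechlor_timecourse"))
  if (exact) {
    i <- which(abs(tc$times - at) < 1e-9)
    if (!length(i)) stop(sprintf("no profile at day %g for system %s", at,
                                 tc$system), call. = FALSE)
    return(tc$profiles[[i[1]]])
  }
  i <- which(tc$times <= at + 1e-9)
  if (!length(i)) stop(sprintf("no profile at or before day %g", at), call. = FALSE)
  tc$profiles[[max(i)]]
}

#' Read congener time courses from long-format CSV
#'
#' Expects columns `system`, `time_d`, `congener`, `mole_percent`; the
#' congener field accepts BZ numbers or structure strings.
#'
#' @param path CSV file path.
#' @param mass_conc_mg_l mixture mass concentration passed to
#'   [dechlor_timecourse()].
#' @return Named list of `"dechlor_timecourse"` objects, one per system.
#' @export
read_congener_csv <- function(path, mass_conc_mg_l = 25) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("system", "time_d", "congener", "mole_percent")
  if (!all(need %in% names(df))) {
    stop(sprintf("missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  }
  out <- lapply(split(df, df$system), function(d) {
    profs <- lapply(split(d, d$time_d), function(dd) {
      congener_profile(dd$congener, dd$mole_percent,
                       time = dd$time_d[1], system = dd$system[1])
    })
    profs <- profs[order(as.numeric(names(profs)))]
    dechlor_timecourse(unname(profs), mass_conc_mg_l = mass_conc_mg_l)
  })
  out
}

#' Write a time course (or list of them) as long-format CSV
#'
#' @param tc a `"dechlor_timecourse"` or list of them.
#' @param path output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_congener_csv <- function(tc, path) {
  if (inherits(tc, "dechlor_timecourse")) tc <- list(tc)
  rows <- lapply(tc, function(one) {
    do.call(rbind, lapply(one$profiles, function(p) {
      data.frame(system = p$system, time_d = p$time,
                 congener = as.integer(names(p$mole_percent)),
                 mole_percent = unname(p$mole_percent))
    }))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
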