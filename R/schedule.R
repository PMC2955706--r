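#' Piecewise-constant light schedules
#'
#' A light schedule is the sole energy input of the model: an ordered set of
#' contiguous segments, each with a constant photosynthetically active
#' radiation (PAR). The first segment starts at time zero and the last
#' segment may be open-ended (`t_end = Inf`). A schedule whose last segment
#' ends at a finite time is implicitly extended by darkness.
#'
#' @param t_start,t_end Segment boundaries in hours; equal-length numeric
#'   vectors, contiguous (`t_end[i] == t_start[i + 1]`), first start at 0.
#' @param par PAR of each segment (umol m-2 s-1, non-negative).
#' @return An object of class `light_schedule`: a data frame with columns
#'   `t_start`, `t_end`, `par`.
#' @seealso [schedule_LL()], [schedule_LD()], [schedule_LDL()],
#'   [schedule_L1L2()]
#' @export
light_schedule <- function(t_start, t_end, par) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(par),
            length(t_start) == length(t_end),
            length(t_start) == length(par),
            length(t_start) >= 1L)
  if (t_start[1L] != 0)
    stop("first segment must start at time 0", call. = FALSE)
  if (any(t_end <= t_start))
    stop("each segment must have t_end > t_start", call. = FALSE)
  n <- length(t_start)
  if (n > 1L) {
    if (any(is.infinite(t_end[-n])))
      stop("only the final segment may be open-ended", call. = FALSE)
    if (any(abs(t_start[-1L] - t_end[-n]) > 1e-9))
      stop("segments must be contiguous and non-overlapping", call. = FALSE)
  }
  if (any(!is.finite(par)) || any(par < 0))
    stop("par must be finite and non-negative", call. = FALSE)
  out <- data.frame(t_start = as.numeric(t_start),
                    t_end = as.numeric(t_end),
                    par = as.numeric(par))
  class(out) <- c("light_schedule", "data.frame")
  out
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("Light schedule (%s), %d segment(s):\n",
              schedule_condition(x), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Shorthand schedule constructors
#'
#' The four illumination regimes used throughout: continuous light (LL),
#' light then permanent darkness (LD), light--dark--light at the same PAR
#' (LDL), and a PAR step between two light levels (L1L2).
#'
#' @param par,par1,par2 PAR levels (umol m-2 s-1).
#' @param t_off Time at which the light is switched off (h).
#' @param t_on Time at which the light is switched back on (h), `> t_off`.
#' @param t_switch Time of the PAR step (h).
#' @return A [light_schedule()].
#' @export
schedule_LL <- function(par) {
  light_schedule(0, Inf, par)
}

#' @rdname schedule_LL
#' @export
schedule_LD <- function(par, t_off) {
  stopifnot(t_off > 0)
  light_schedule(c(0, t_off), c(t_off, Inf), c(par, 0))
}

#' @rdname schedule_LL
#' @export
schedule_LDL <- function(par, t_off, t_on) {
  stopifnot(t_off > 0, t_on > t_off)
  light_schedule(c(0, t_off, t_on), c(t_off, t_on, Inf), c(par, 0, par))
}

#' @rdname schedule_LL
#' @export
schedule_L1L2 <- function(par1, t_switch, par2) {
  stopifnot(t_switch > 0, par1 > 0, par2 > 0)
  light_schedule(c(0, t_switch), c(t_switch, Inf), c(par1, par2))
}

#' PAR at a given time
#'
#' @param schedule A [light_schedule()].
#' @param t Time(s) in hours, non-negative. Times beyond a finite schedule
#'   end are treated as darkness.
#' @return PAR value(s).
#' @export
par_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "light_schedule"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  idx <- findInterval(t, schedule$t_start)
  par <- schedule$par[idx]
  par[t >= schedule$t_end[idx]] <- 0  # beyond a finite schedule: darkness
  par
}

#' Classify a schedule into one of the four experimental conditions
#'
#' Labels follow the illumination regimes: a single light level throughout
#' is `"LL"`; light followed by a terminal dark segment is `"LD"`; light,
#' dark, then light again at the same PAR is `"LDL"`; two successive light
#' levels with no intervening darkness is `"L1L2"`. Anything else is
#' labelled `"other"`.
#'
#' @param schedule A [light_schedule()].
#' @param dark_par PAR at or below which a segment counts as dark.
#' @return A character scalar.
#' @export
schedule_condition <- function(schedule, dark_par = 0) {
  stopifnot(inherits(schedule, "light_schedule"))
  is_dark <- schedule$par <= dark_par
  pars <- schedule$par
  n <- nrow(schedule)
  if (!any(is_dark) && length(unique(pars)) == 1L) return("LL")
  if (n == 2L && !is_dark[1L] && is_dark[2L]) return("LD")
  if (n == 3L && !is_dark[1L] && is_dark[2L] && !is_dark[3L] &&
      pars[1L] == pars[3L]) return("LDL")
  if (n == 2L && !any(is_dark) && pars[1L] != pars[2L]) return("L1L2")
  "other"
}

#' Read or write a light schedule as JSON
#'
#' Format: `{"segments": [{"t_start": 0, "t_end": 10, "par": 200}, ...]}`;
#' an open-ended final segment is stored with the string `"Inf"`.
#'
#' @param path File path.
#' @return `read_schedule()` returns a `light_schedule`;
#'   `write_schedule()` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- obj$segments
  if (is.null(seg) || !is.data.frame(seg))
    stop("schedule file must contain a 'segments' array", call. = FALSE)
  t_end <- seg$t_end
  if (is.character(t_end)) t_end <- as.numeric(t_end)  # "Inf" -> Inf
  light_schedule(seg$t_start, t_end, seg$par)
}

#' @rdname read_schedule
#' @param schedule A `light_schedule` to serialise.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "light_schedule"))
  seg <- as.data.frame(schedule)
  seg$t_end <- ifelse(is.finite(seg$t_end), seg$t_end, "Inf")
  jsonlite::write_json(list(segments = seg), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
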