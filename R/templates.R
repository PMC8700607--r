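#' Peak specification
#'
#' One Gaussian peak of a class fingerprint template: retention time on the
#' 0--25 min run, Gaussian sigma, and one amplitude per detection channel
#' (UV absorbance at 280 nm, FLD fluorescence at 280/350 nm; arbitrary units).
#'
#' @param rt_min Retention time in minutes, in `[0, 25]`.
#' @param width_min Gaussian sigma in minutes, `> 0`.
#' @param amp_uv,amp_fld Non-negative channel amplitudes; an amplitude of 0
#'   means the compound is silent in that channel.
#' @return A `peak_spec` object (named list).
#' @export
peak_spec <- function(rt_min, width_min, amp_uv, amp_fld) {
  stopifnot(is.numeric(rt_min), is.numeric(width_min),
            is.numeric(amp_uv), is.numeric(amp_fld))
  if (rt_min < 0 || rt_min > 25) {
    stop("rt_min must lie within the 0-25 min run", call. = FALSE)
  }
  if (width_min <= 0) stop("width_min must be > 0", call. = FALSE)
  if (amp_uv < 0 || amp_fld < 0) {
    stop("peak amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(rt_min = rt_min, width_min = width_min,
                 amp_uv = amp_uv, amp_fld = amp_fld),
            class = "peak_spec")
}

#' Class fingerprint template
#'
#' The generative description of one sample class: its peak pattern plus the
#' lot-to-lot amplitude variability (lognormal coefficient of variation) and
#' the per-injection retention-time jitter.
#'
#' White tea is modelled as two sub-templates (`white_a`, `white_b`) that both
#' carry the external class label `"white"`: commercial white teas come from
#' two distinct productions and cluster in two groups, one of them close to
#' chicory.
#'
#' @param class_name One of `black`, `green`, `oolong`, `red`, `white_a`,
#'   `white_b`, `chicory`.
#' @param peaks A list of [peak_spec()] objects or a data frame with columns
#'   `rt_min`, `width_min`, `amp_uv`, `amp_fld`.
#' @param amp_cv Lot-to-lot lognormal coefficient of variation of peak
#'   amplitudes (unitless, `>= 0`).
#' @param rt_jitter_sd Per-injection retention shift s.d. in minutes (`>= 0`).
#' @return A `class_template` object.
#' @export
class_template <- function(class_name, peaks, amp_cv = 0.05,
                           rt_jitter_sd = 0.02) {
  valid <- c("black", "green", "oolong", "red", "white_a", "white_b", "chicory")
  class_name <- match.arg(class_name, valid)
  if (amp_cv < 0) stop("amp_cv must be >= 0", call. = FALSE)
  if (rt_jitter_sd < 0) stop("rt_jitter_sd must be >= 0", call. = FALSE)
  if (is.data.frame(peaks)) {
    peaks <- lapply(seq_len(nrow(peaks)), function(i) {
      peak_spec(peaks$rt_min[i], peaks$width_min[i],
                peaks$amp_uv[i], peaks$amp_fld[i])
    })
  }
  stopifnot(length(peaks) >= 1L,
            all(vapply(peaks, inherits, logical(1), "peak_spec")))
  structure(list(class_name = class_name, peaks = peaks, amp_cv = amp_cv,
                 rt_jitter_sd = rt_jitter_sd),
            class = "class_template")
}

#' External (reported) class label of a template
#'
#' Maps the two white-tea sub-templates onto the single label `"white"`; all
#' other templates keep their own name.
#'
#' @param class_name Template class name.
#' @return Character label used in metadata and classification.
#' @export
external_label <- function(class_name) {
  ifelse(class_name %in% c("white_a", "white_b"), "white", class_name)
}

peak_field <- function(template, field) {
  vapply(template$peaks, `[[`, numeric(1), field)
}

#' Default class templates for the tea / chicory study
#'
#' Encodes the qualitative fingerprint structure observed across the six
#' sample classes:
#' \itemize{
#'   \item every tea shares an intense UV peak near 11 min;
#'   \item chicory gives the richest UV fingerprint but with peak intensities
#'     about 100-fold lower than any tea;
#'   \item white tea gives the most intense UV profiles, black and green the
#'     most intense FLD signals;
#'   \item red tea and chicory give the most peak-rich FLD fingerprints;
#'   \item white tea splits into two sub-templates, `white_b` carrying a
#'     couple of low-intensity peaks at chicory retention times.
#' }
#'
#' @param amp_cv Lot-to-lot amplitude coefficient of variation applied to all
#'   templates (default 0.05).
#' @param rt_jitter_sd Per-injection retention jitter s.d. in minutes
#'   (default 0.02).
#' @return Named list of [class_template()] objects, one per class.
#' @export
build_default_templates <- function(amp_cv = 0.05, rt_jitter_sd = 0.02) {
  df <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(rt_min = m[, 1], width_min = m[, 2],
               amp_uv = m[, 3], amp_fld = m[, 4])
  }
  peaks <- list(
    black = df(
      3.2, 0.08, 30, 55,
      5.1, 0.07, 25, 70,
      6.8, 0.09, 40, 85,
      8.4, 0.08, 35, 40,
      11.0, 0.10, 62, 60,
      13.5, 0.08, 28, 35,
      15.2, 0.09, 18, 20,
      17.1, 0.10, 12, 15),
    green = df(
      2.8, 0.07, 28, 60,
      4.6, 0.08, 32, 80,
      6.2, 0.08, 45, 75,
      7.9, 0.07, 30, 45,
      9.4, 0.09, 22, 30,
      11.1, 0.10, 58, 65,
      14.0, 0.09, 20, 25,
      16.3, 0.10, 10, 12),
    oolong = df(
      3.8, 0.08, 18, 20,
      7.2, 0.09, 25, 38,
      9.8, 0.08, 0, 22,
      11.0, 0.10, 40, 30,
      12.6, 0.08, 15, 14,
      18.0, 0.10, 8, 0),
    red = df(
      2.4, 0.07, 20, 30,
      4.2, 0.08, 0, 42,
      5.9, 0.08, 35, 50,
      8.8, 0.09, 26, 38,
      11.2, 0.10, 46, 45,
      13.0, 0.08, 0, 35,
      14.8, 0.09, 18, 28,
      16.8, 0.08, 0, 40,
      19.5, 0.10, 0, 25,
      21.0, 0.09, 12, 18,
      22.5, 0.10, 0, 15),
    white_a = df(
      3.5, 0.08, 55, 25,
      6.5, 0.09, 70, 45,
      9.0, 0.08, 45, 30,
      11.0, 0.10, 100, 40,
      15.5, 0.09, 30, 12),
    white_b = df(
      3.5, 0.08, 48, 20,
      5.5, 0.08, 2.5, 8,
      6.5, 0.09, 60, 38,
      9.0, 0.08, 38, 26,
      11.0, 0.10, 92, 34,
      12.2, 0.08, 2.0, 6,
      15.5, 0.09, 24, 10),
    chicory = df(
      1.8, 0.07, 0.18, 18,
      3.0, 0.08, 0.25, 25,
      4.4, 0.08, 0.32, 30,
      5.5, 0.08, 0.30, 28,
      7.0, 0.09, 0.22, 22,
      8.2, 0.08, 0.28, 26,
      9.6, 0.08, 0.20, 20,
      10.4, 0.09, 0.26, 24,
      12.2, 0.08, 0.31, 29,
      14.4, 0.09, 0.15, 15,
      16.0, 0.10, 0.12, 12,
      18.5, 0.10, 0.10, 10)
  )
  # Minor-peak background: real tea/chicory fingerprints carry dozens of
  # small, partially resolved signals besides the major peaks. Each class
  # gets a fixed set of low-amplitude peaks (2-10% of its channel maxima) at
  # class-specific positions, built once from a constant internal seed so the
  # default templates are the same on every call. Counts preserve the class
  # orderings: chicory stays the UV-richest fingerprint, red and chicory the
  # FLD-richest.
  n_minor <- c(black = 14, green = 14, oolong = 10, red = 10,
               white_a = 10, white_b = 10, chicory = 20)
  fld_extra <- c(red = 10, chicory = 0)  # red's FLD-only minor peaks
  out <- lapply(names(peaks), function(nm) {
    main <- peaks[[nm]]
    minor <- with_seed(20210 + match(nm, names(peaks)), {
      k <- n_minor[[nm]]
      ke <- if (nm %in% names(fld_extra)) fld_extra[[nm]] else 0L
      pos <- stats::runif(k + ke, 1.5, 23)
      data.frame(
        rt_min = pos,
        width_min = stats::runif(k + ke, 0.08, 0.15),
        amp_uv = c(stats::runif(k, 0.02, 0.10), numeric(ke)) * max(main$amp_uv),
        amp_fld = stats::runif(k + ke, 0.02, 0.10) * max(main$amp_fld))
    })
    class_template(nm, rbind(main, minor), amp_cv = amp_cv,
                   rt_jitter_sd = rt_jitter_sd)
  })
  names(out) <- names(peaks)
  out
}
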