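#' Structural homogeneity from percent void volume
#'
#' `HS = 100 - void volume (%)`: a sample without voids is structurally
#' perfectly homogeneous.
#'
#' @param void_percent Percent void volume in `[0, 100]` (vectorized).
#' @return HS in percent.
#' @export
structural_homogeneity <- function(void_percent) {
  if (!is.numeric(void_percent) || any(!is.finite(void_percent)) ||
      any(void_percent < 0 | void_percent > 100)) {
    stop_input("`void_percent` must lie in [0, 100].")
  }
  100 - void_percent
}

#' FLIm lifetime homogeneity of a sample
#'
#' Fraction (in percent) of the lifetime distribution lying within
#' `mean * (1 - f)` to `mean * (1 + f)`, i.e. the area under the probability
#' density function of the per-pixel lifetimes over a window of +/- `f` times
#' the average lifetime (default f = 0.1). The area under the entire PDF is
#' 100%, so a window spanning the full observed range returns exactly 100.
#'
#' By default the empirical distribution is used: the area over an interval is
#' exactly the fraction of pixels inside it (closed interval). A Gaussian
#' kernel density option (Silverman bandwidth) is available for sensitivity
#' checks.
#'
#' @param lt Numeric vector of lifetimes (ns), or a `lifetime_map` whose
#'   valid pixels are used.
#' @param window_fraction Half-width of the window as a fraction of the mean.
#' @param method `"empirical"` (default) or `"kde"`.
#' @return Homogeneity in percent, in `[0, 100]`.
#' @export
#' @examples
#' flim_homogeneity(rnorm(1000, mean = 4, sd = 0.2))
flim_homogeneity <- function(lt, window_fraction = 0.1,
                             method = c("empirical", "kde")) {
  method <- match.arg(method)
  if (inherits(lt, "lifetime_map")) lt <- map_values(lt)
  lt <- lt[is.finite(lt)]
  if (length(lt) < 10L) {
    abort("Need at least 10 valid lifetime values.",
          class = "tissueqc_insufficient_data")
  }
  check_number(window_fraction, "window_fraction", lower = 0,
               strict_lower = TRUE)
  mu <- mean(lt)
  lo <- mu * (1 - window_fraction)
  hi <- mu * (1 + window_fraction)
  if (method == "empirical") {
    100 * mean(lt >= lo & lt <= hi)
  } else {
    if (sd(lt) == 0) return(100)
    d <- density(lt, bw = "nrd0", n = 2048, cut = 4)
    # trapezoidal areas, window area normalized by total area
    trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
    xs <- pmin(pmax(d$x, lo), hi)
    100 * trap(xs, d$y) / trap(d$x, d$y)
  }
}

#' Combined imaging-based homogeneity index
#'
#' Equal-weight (1:1) combination of structural homogeneity from ultrasound
#' and the mean biochemical homogeneity from the two FLIm channels:
#' `HI = 1/2 * (HS + 1/2 * (HF2 + HF3))`. A perfectly homogeneous material
#' scores 100%.
#'
#' @param hs Structural homogeneity, percent.
#' @param hf2,hf3 FLIm channel-2 and channel-3 homogeneity, percent.
#' @return HI in percent (vectorized).
#' @export
#' @examples
#' homogeneity_index(80, 60, 40) # 65
homogeneity_index <- function(hs, hf2, hf3) {
  vals <- c(hs, hf2, hf3)
  if (!is.numeric(vals) || any(!is.finite(vals)) ||
      any(vals < 0 | vals > 100)) {
    stop_input("`hs`, `hf2`, `hf3` must lie in [0, 100].")
  }
  0.5 * (hs + 0.5 * (hf2 + hf3))
}

#' Homogeneity summary for one sample at one time point
#'
#' Computes HS from the void percentage, HF2/HF3 from the channel-2 and
#' channel-3 lifetime maps (whole-sample valid pixels: homogeneity is a
#' whole-sample property), and the combined index HI.
#'
#' @param ch2,ch3 `lifetime_map` objects (or numeric lifetime vectors) for
#'   channels 2 and 3.
#' @param void_percent Percent void volume from [void_volumetry()].
#' @param sample_id,day Optional identifiers carried into the output.
#' @param window_fraction Passed to [flim_homogeneity()].
#' @return A one-row tibble: `sample_id`, `day`, `hs`, `hf2`, `hf3`, `hi`.
#' @export
homogeneity_result <- function(ch2, ch3, void_percent, sample_id = NA_character_,
                               day = NA_real_, window_fraction = 0.1) {
  hs <- structural_homogeneity(void_percent)
  hf2 <- flim_homogeneity(ch2, window_fraction)
  hf3 <- flim_homogeneity(ch3, window_fraction)
  tibble(
    sample_id = sample_id, day = day,
    hs = hs, hf2 = hf2, hf3 = hf3,
    hi = homogeneity_index(hs, hf2, hf3)
  )
}
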