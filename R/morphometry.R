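# Rod outer segment length morphometry: 2-um histogram with normalized
# frequencies, single / two-component Gaussian fits on bin centres, and the
# component-area bookkeeping used to report the fraction of long outer
# segments.

#' Build a normalized length histogram
#'
#' Counts lengths into right-open bins `[k*w, (k+1)*w)` aligned to multiples
#' of the bin width starting at 0 and divides by the total count, so the
#' frequencies sum to 1.
#'
#' @param lengths Positive lengths, um.
#' @param bin_width Bin width, um (default 2).
#' @return A list of class `ros_histogram`: `edges` (length nbins+1),
#'   `centers`, `frequencies` (sum 1), `n`.
#' @examples
#' build_histogram(c(1, 1, 3))$frequencies  # 2/3, 1/3
#' @export
build_histogram <- function(lengths, bin_width = 2) {
  if (length(lengths) == 0) stop("no lengths supplied")
  stopifnot(all(lengths > 0), bin_width > 0)
  edges <- seq(0, bin_width * (floor(max(lengths) / bin_width) + 1),
               by = bin_width)
  counts <- tabulate(findInterval(lengths, edges), nbins = length(edges) - 1)
  structure(list(edges = edges, centers = edges[-1] - bin_width / 2,
                 frequencies = counts / length(lengths), n = length(lengths)),
            class = "ros_histogram")
}

#' Closed-form Gaussian peak area
#'
#' Area under a Gaussian of the given height and FWHM:
#' `height * FWHM * sqrt(pi / (4 ln 2))`; identical to the integral of
#' `height * exp(-4 ln 2 (x - c)^2 / FWHM^2)`.
#'
#' @param height Peak height (>= 0).
#' @param fwhm Full width at half maximum (> 0).
#' @return Area in height x um units.
#' @examples
#' gaussian_area(0.22, 7.2)  # ~1.7
#' @export
gaussian_area <- function(height, fwhm) {
  stopifnot(all(height >= 0), all(fwhm > 0))
  height * fwhm * sqrt(pi / (4 * log(2)))
}

# Gaussian in height/FWHM parameterisation
.gauss_hw <- function(x, center, fwhm, height)
  height * exp(-4 * log(2) * (x - center)^2 / fwhm^2)

#' Fit one or two Gaussian components to a length histogram
#'
#' Least-squares fit of a sum of `k` Gaussians (centre, FWHM, height) to the
#' (bin centre, normalized frequency) pairs; empty bins participate with
#' frequency 0. For `k = 2` the components are initialised by 2-means on a
#' frequency-weighted pseudo-sample of the bin centres and returned ordered
#' by centre; a fit whose centres collapse within one bin width is flagged.
#'
#' @param hist A `ros_histogram` (see [build_histogram()]) with at least
#'   `2k + 2` non-empty bins.
#' @param k 1 or 2 components.
#' @return A list of class `gaussian_fit`: `components` (data frame with
#'   `center`, `fwhm`, `height`, `area`), `k`, `collapsed`,
#'   `residual_norm`.
#' @export
fit_gaussians <- function(hist, k = 1) {
  stopifnot(inherits(hist, "ros_histogram"), k %in% c(1, 2))
  x <- hist$centers; y <- hist$frequencies
  if (sum(y > 0) < 2 * k + 2)
    stop(sprintf("need at least %d non-empty bins for k = %d", 2 * k + 2, k))
  bw <- diff(hist$edges)[1]
  wm <- sum(x * y); wsd <- sqrt(sum(y * (x - wm)^2))
  if (k == 1) {
    st <- list(c1 = wm, w1 = sd_to_fwhm(wsd), h1 = max(y))
    fit <- minpack.lm::nlsLM(y ~ .gauss_hw(x, c1, w1, h1),
                             data = data.frame(x = x, y = y), start = st,
                             lower = c(min(x), bw / 2, 0))
    p <- stats::coef(fit)
    comp <- data.frame(center = p[["c1"]], fwhm = p[["w1"]], height = p[["h1"]])
  } else {
    pseudo <- rep(x, round(y * 1e4))
    km <- stats::kmeans(pseudo, centers = 2, nstart = 5)
    ord <- order(km$centers)
    ctr <- as.numeric(km$centers)[ord]
    wd <- vapply(ord, function(g) {
      s <- stats::sd(pseudo[km$cluster == g])
      if (!is.finite(s) || s < bw / 2) bw else sd_to_fwhm(s)
    }, numeric(1))
    ht <- vapply(ctr, function(cc) max(y[which.min(abs(x - cc))], max(y) / 10),
                 numeric(1))
    st <- list(c1 = ctr[1], w1 = wd[1], h1 = ht[1],
               c2 = ctr[2], w2 = wd[2], h2 = ht[2])
    fit <- minpack.lm::nlsLM(
      y ~ .gauss_hw(x, c1, w1, h1) + .gauss_hw(x, c2, w2, h2),
      data = data.frame(x = x, y = y), start = st,
      lower = c(min(x), bw / 2, 0, min(x), bw / 2, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- stats::coef(fit)
    comp <- data.frame(center = c(p[["c1"]], p[["c2"]]),
                       fwhm = c(p[["w1"]], p[["w2"]]),
                       height = c(p[["h1"]], p[["h2"]]))
    comp <- comp[order(comp$center), ]
    rownames(comp) <- NULL
  }
  comp$area <- gaussian_area(comp$height, comp$fwhm)
  collapsed <- k == 2 && diff(comp$center) < bw
  if (collapsed) warning("two-component fit collapsed: centres within one bin")
  structure(list(components = comp, k = k, collapsed = collapsed,
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> %d component(s)%s\n", x$k,
              if (x$collapsed) " [collapsed]" else ""))
  print(format(x$components, digits = 3))
  invisible(x)
}

#' Area fraction of the longer-mean component
#'
#' For a two-component fit, the fitted area of the larger-centre component
#' divided by the total fitted area: the fraction of outer segments in the
#' long-length population.
#'
#' @param components Data frame with `center` and `area` for exactly two
#'   components (e.g. `fit_gaussians(h, 2)$components`).
#' @return Fraction in [0, 1].
#' @examples
#' area_fraction(data.frame(center = c(26.8, 34), area = c(1.67, 0.51)))
#' @export
area_fraction <- function(components) {
  if (inherits(components, "gaussian_fit")) components <- components$components
  stopifnot(nrow(components) == 2)
  total <- sum(components$area)
  if (total <= 0) stop("zero total fitted area")
  components$area[which.max(components$center)] / total
}

#' Compare two groups of lengths
#'
#' Percent difference of group means, `(mean_b - mean_a)/mean_a * 100`, with
#' an unpaired two-tailed t test.
#'
#' @param lengths_a,lengths_b Numeric vectors, each n >= 2 (group a is the
#'   reference, e.g. wild-type).
#' @param var_equal Pooled-variance t test if `TRUE` (classic unpaired
#'   t test), Welch otherwise.
#' @return A list: `percent_difference`, `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
compare_group_means <- function(lengths_a, lengths_b, var_equal = TRUE) {
  stopifnot(length(lengths_a) >= 2, length(lengths_b) >= 2)
  ma <- mean(lengths_a); mb <- mean(lengths_b)
  if (ma == 0) stop("reference group mean is zero; percent difference undefined")
  tt <- stats::t.test(lengths_b, lengths_a, var.equal = var_equal)
  list(percent_difference = (mb - ma) / ma * 100, mean_a = ma, mean_b = mb,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
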