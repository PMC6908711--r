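# Baseline colour skin classifiers, data-augmentation transforms, and the
# loss/metric functions of the segmentation network.

LOG_EPS <- 1e-12

clamp_prob <- function(p) pmin(pmax(p, LOG_EPS), 1 - LOG_EPS)

#' Intersection-over-union of two binary masks
#'
#' `|intersection| / |union|` of the predicted and ground-truth skin labels.
#' Both masks empty gives 1 (perfect agreement on the absence of skin); one
#' empty mask gives 0.
#'
#' @param y_p,y_g Logical (or 0/1) matrices of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(y_p, y_g) {
  if (!identical(dim(y_p), dim(y_g)))
    stop("mask shapes differ: ", paste(dim(y_p), collapse = "x"), " vs ",
         paste(dim(y_g), collapse = "x"))
  a <- y_p != 0
  b <- y_g != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Patient-detection loss
#'
#' Multinomial logistic (cross-entropy) loss of the two-class softmax
#' detection output against the one-hot presence label:
#' `-b0*log(d0) - b1*log(d1)`, with scores clamped away from 0 and 1.
#'
#' @param d Numeric length-2 softmax scores `(d0, d1)`, summing to 1.
#' @param b One-hot ground truth: `c(1, 0)` absent, `c(0, 1)` present.
#' @return Non-negative scalar.
#' @export
detection_loss <- function(d, b) {
  stopifnot(length(d) == 2, length(b) == 2, all(b %in% c(0, 1)), sum(b) == 1)
  d <- clamp_prob(d)
  -sum(b * log(d))
}

#' Class-weighted skin-segmentation loss
#'
#' Pixel-summed cross-entropy with the skin class weighted by
#' `lambda = N_non_skin / N_skin`, compensating the class imbalance of
#' skin labels:
#' `-sum(l0 * log(s0)) - lambda * sum(l1 * log(s1))`.
#'
#' @param s1 Matrix of per-pixel skin-class probabilities (the non-skin
#'   probability is `1 - s1`).
#' @param label Binary ground-truth matrix (1 = skin).
#' @param lambda Class weight; by default derived from `label`. An all-skin
#'   label leaves the weight undefined and is an error.
#' @return Non-negative scalar.
#' @export
segmentation_loss <- function(s1, label, lambda = NULL) {
  if (!identical(dim(s1), dim(label))) stop("shapes differ")
  l1 <- label != 0
  n_skin <- sum(l1)
  n_non <- length(label) - n_skin
  if (is.null(lambda)) {
    if (n_skin == 0)
      stop("label has no skin pixels: class weight N_non_skin/N_skin ",
           "is undefined")
    if (n_non == 0)
      stop("label is all skin: class weight N_non_skin/N_skin degenerates ",
           "to 0, which is not allowed")
    lambda <- n_non / n_skin
  }
  s1c <- clamp_prob(s1)
  -sum(log(1 - s1c)[!l1]) - lambda * sum(log(s1c)[l1])
}

#' Unified multi-task loss
#'
#' Weighted sum of the detection and segmentation losses,
#' `alpha_det * det_loss + alpha_seg * seg_loss`. Stage-one segmentation
#' training corresponds to `alpha_det = 0, alpha_seg = 1`; joint training
#' weights both tasks equally.
#'
#' @param det_loss,seg_loss Non-negative task losses.
#' @param alpha_det,alpha_seg Non-negative task weights.
#' @return Scalar loss.
#' @export
unified_loss <- function(det_loss, seg_loss, alpha_det = 1, alpha_seg = 1) {
  if (alpha_det < 0 || alpha_seg < 0) stop("weights must be non-negative")
  stopifnot(det_loss >= 0, seg_loss >= 0)
  alpha_det * det_loss + alpha_seg * seg_loss
}

#' Train a baseline colour skin classifier
#'
#' Pixel-wise classifiers operating on raw RGB values: a histogram Naive
#' Bayes model (32 bins per channel per class, Laplace smoothed) or
#' Gaussian mixture models (3 full-covariance components per class,
#' fixed-seed EM via \pkg{mclust}).
#'
#' @param pixels Numeric matrix (n x 3) of RGB values in [0, 255].
#' @param labels Binary vector (1 = skin); both classes must be present.
#' @param kind `"naive_bayes"` or `"gmm"`.
#' @param n_components GMM components per class.
#' @param n_bins Histogram bins per channel for Naive Bayes.
#' @param seed RNG seed for EM initialisation.
#' @return Object of class `pixel_colour_model`.
#' @export
train_colour_model <- function(pixels, labels, kind = c("gmm", "naive_bayes"),
                               n_components = 3, n_bins = 32, seed = 1L) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 3, nrow(pixels) == length(labels))
  labels <- as.integer(labels != 0)
  for (cls in 0:1)
    if (!any(labels == cls))
      stop("class ", c("non-skin", "skin")[cls + 1],
           " is not represented in the training pixels")
  priors <- c(mean(labels == 0), mean(labels == 1))
  if (kind == "naive_bayes") {
    breaks <- seq(0, 256, length.out = n_bins + 1)
    hists <- lapply(0:1, function(cls) {
      px <- pixels[labels == cls, , drop = FALSE]
      lapply(1:3, function(ch) {
        h <- tabulate(findInterval(px[, ch], breaks, all.inside = TRUE),
                      nbins = n_bins)
        (h + 1) / (sum(h) + n_bins)   # Laplace smoothing
      })
    })
    model <- list(kind = kind, priors = priors, breaks = breaks,
                  hists = hists, n_bins = n_bins)
  } else {
    fits <- lapply(0:1, function(cls) {
      px <- pixels[labels == cls, , drop = FALSE]
      G <- min(n_components, nrow(px))
      fit <- with_local_seed(seed, mclust::densityMclust(
        px, G = G, modelNames = "VVV", verbose = FALSE, plot = FALSE))
      if (is.null(fit))   # saturated channels give singular covariances;
        fit <- with_local_seed(seed, mclust::densityMclust(
          px, G = G, verbose = FALSE, plot = FALSE))
      if (is.null(fit)) { # last resort: break the degeneracy with jitter
        pj <- px + with_local_seed(seed,
                                   matrix(stats::rnorm(length(px), 0, 0.01),
                                          nrow(px)))
        fit <- with_local_seed(seed, mclust::densityMclust(
          pj, G = G, verbose = FALSE, plot = FALSE))
      }
      if (is.null(fit))
        stop("GMM fit failed for the ",
             c("non-skin", "skin")[cls + 1], " class")
      fit
    })
    model <- list(kind = kind, priors = priors, fits = fits)
  }
  structure(model, class = "pixel_colour_model")
}

log_density <- function(model, pixels, cls) {
  if (model$kind == "naive_bayes") {
    ll <- 0
    for (ch in 1:3) {
      bins <- findInterval(pixels[, ch], model$breaks, all.inside = TRUE)
      ll <- ll + log(model$hists[[cls + 1]][[ch]][bins])
    }
    ll
  } else {
    fit <- model$fits[[cls + 1]]
    log(pmax(mclust::predict.densityMclust(fit, newdata = pixels),
             .Machine$double.xmin))
  }
}

#' Classify skin pixels in a frame
#'
#' Computes a per-pixel skin probability map from a fitted colour model
#' (posterior `p(skin | RGB)` under the class priors) and thresholds it to a
#' binary mask.
#'
#' @param frame rows x cols x 3 intensity array.
#' @param model A [train_colour_model()] fit.
#' @param threshold Skin-probability threshold in `[0, 1]`.
#' @return List with `probability` (matrix of `p(skin)`), `mask` (logical
#'   matrix, `probability >= threshold`), `n_skin`, `n_non_skin`.
#' @export
classify_skin <- function(frame, model, threshold = 0.5) {
  stopifnot(inherits(model, "pixel_colour_model"),
            threshold >= 0, threshold <= 1)
  d <- dim(frame)
  px <- cbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
              as.vector(frame[, , 3]))
  l0 <- log_density(model, px, 0) + log(model$priors[1])
  l1 <- log_density(model, px, 1) + log(model$priors[2])
  m <- pmax(l0, l1)
  p1 <- exp(l1 - m) / (exp(l0 - m) + exp(l1 - m))
  prob <- matrix(p1, d[1], d[2])
  mask <- prob >= threshold
  list(probability = prob, mask = mask,
       n_skin = sum(mask), n_non_skin = sum(!mask))
}

# RGB [0,255] <-> HSL conversions (vectorised over matrices).
rgb_to_hsl <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- rep(0, length(r))
  i <- d > 0 & mx == r
  h[i] <- ((g[i] - b[i]) / d[i]) %% 6
  i <- d > 0 & mx == g & mx != r
  h[i] <- (b[i] - r[i]) / d[i] + 2
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- (r[i] - g[i]) / d[i] + 4
  list(h = h * 60, s = s, l = l)
}

hsl_to_rgb <- function(h, s, l) {
  c_ <- (1 - abs(2 * l - 1)) * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c_ / 2
  r <- g <- b <- rep(0, length(h))
  seg <- floor((h %% 360) / 60)
  r[seg == 0] <- c_[seg == 0]; g[seg == 0] <- x[seg == 0]
  r[seg == 1] <- x[seg == 1]; g[seg == 1] <- c_[seg == 1]
  g[seg == 2] <- c_[seg == 2]; b[seg == 2] <- x[seg == 2]
  g[seg == 3] <- x[seg == 3]; b[seg == 3] <- c_[seg == 3]
  r[seg == 4] <- x[seg == 4]; b[seg == 4] <- c_[seg == 4]
  r[seg == 5] <- c_[seg == 5]; b[seg == 5] <- x[seg == 5]
  list(r = (r + m) * 255, g = (g + m) * 255, b = (b + m) * 255)
}

#' Augment a video frame
#'
#' The augmentation transforms used when training the segmentation network:
#' rotation about the image centre in 45-degree increments (bilinear
#' interpolation, zero padding), mirroring about the centre on the x or y
#' axis, and lighting adjustment performed by scaling the lightness
#' component in HSL colour space.
#'
#' @param frame rows x cols x 3 intensity array in [0, 255].
#' @param mode `"rotate"`, `"mirror_x"`, `"mirror_y"` or `"lighting"`.
#' @param parameter Rotation angle in degrees (multiple of 45) or positive
#'   lightness scale factor.
#' @return Transformed frame of the same shape.
#' @export
augment_image <- function(frame, mode = c("rotate", "mirror_x", "mirror_y",
                                          "lighting"),
                          parameter = NULL) {
  mode <- match.arg(mode)
  d <- dim(frame)
  if (mode == "rotate") {
    ang <- parameter %% 360
    if (ang %% 45 != 0)
      stop("rotation must be a multiple of 45 degrees")
    if (ang == 0) return(frame)
    img <- EBImage::Image(aperm(frame, c(2, 1, 3)) / 255, colormode = "Color")
    rot <- EBImage::rotate(img, ang, filter = "bilinear",
                           output.dim = c(d[2], d[1]), bg.col = "black")
    out <- aperm(EBImage::imageData(rot), c(2, 1, 3)) * 255
    return(out)
  }
  if (mode == "mirror_x") return(frame[, d[2]:1, , drop = FALSE])
  if (mode == "mirror_y") return(frame[d[1]:1, , , drop = FALSE])
  # lighting
  if (is.null(parameter) || parameter <= 0)
    stop("lighting factor must be positive")
  hsl <- rgb_to_hsl(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
                    as.vector(frame[, , 3]))
  l <- pmin(pmax(hsl$l * parameter, 0), 1)
  rgb <- hsl_to_rgb(hsl$h, hsl$s, l)
  out <- array(0, d)
  out[, , 1] <- pmin(pmax(rgb$r, 0), 255)
  out[, , 2] <- pmin(pmax(rgb$g, 0), 255)
  out[, , 3] <- pmin(pmax(rgb$b, 0), 255)
  out
}
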