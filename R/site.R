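#' Describe a fascicle in the nerve cross-section
#'
#' @param name fascicle name (e.g. `"tibial"`).
#' @param center numeric length-2, (x, y) position of the fascicle centre in
#'   mm; the origin is the nerve axis.
#' @param radius fascicle radius in mm.
#' @return a list of class `fascicle_spec`.
#' @export
fascicle_spec <- function(name, center, radius) {
  assert_that(is.character(name) && length(name) == 1L, "name must be a string")
  assert_that(is.numeric(center) && length(center) == 2L, "center must be (x, y)")
  assert_that(is_scalar_num(radius) && radius > 0, "radius must be > 0")
  structure(list(name = name, center = as.numeric(center), radius = radius),
            class = "fascicle_spec")
}

#' Model of the nerve at one implantation site
#'
#' Couples the cross-section fascicle geometry with a class-by-fascicle
#' activation-gain matrix and the parameters of the pickup (lead-field) model.
#' The distal sciatic nerve has clearly separated tibial and peroneal
#' fascicles (plus sural/cutaneous divisions); proximally the nerve is
#' functionally unifascicular, so the default proximal geometry places the
#' same fascicles almost concentrically.
#'
#' The pickup weight of contact *i* for fascicle *f* is
#' `w = (d0 / (d0 + d))^gamma` with `d` the cross-section distance between the
#' contact (on the circle of radius `inner_diameter / 2`) and the fascicle
#' centre. `d0` softens the divergence at zero distance and `gamma` sets the
#' decay; both are modelling stand-ins, not a volume-conductor solution.
#'
#' @param site `"distal"` or `"proximal"`.
#' @param fascicles list of [fascicle_spec()] objects.
#' @param gain_matrix numeric matrix, fascicles x classes, nonnegative
#'   activation gains applied during stimulus ON. Rows must be named after the
#'   fascicles, columns after the stimulus classes.
#' @param baseline_gain nonnegative scalar gain applied during stimulus OFF
#'   (rest-state afferent activity). Default 0.1.
#' @param pickup_d0 softening constant of the pickup model, mm. Default 2.0
#'   (see the methods vignette for why this value, and not a smaller one,
#'   reproduces the ring-versus-point selectivity contrast).
#' @param pickup_gamma decay exponent, dimensionless. Default 2.
#' @param nerve_radius nerve radius in mm, default 0.5 (1.0 mm inner
#'   diameter cuff).
#' @return a list of class `nerve_site_model`.
#' @seealso [default_nerve_site()], [compute_pickup_weights()]
#' @export
nerve_site_model <- function(site = c("distal", "proximal"),
                             fascicles,
                             gain_matrix,
                             baseline_gain = 0.1,
                             pickup_d0 = 2.0,
                             pickup_gamma = 2.0,
                             nerve_radius = 0.5) {
  site <- match.arg(site)
  assert_that(is.list(fascicles) && length(fascicles) >= 1L &&
                all(vapply(fascicles, inherits, TRUE, "fascicle_spec")),
              "fascicles must be a non-empty list of fascicle_spec objects")
  gain_matrix <- as.matrix(gain_matrix)
  assert_that(nrow(gain_matrix) == length(fascicles),
              "gain_matrix must have one row per fascicle")
  assert_that(all(gain_matrix >= 0), "all gains must be >= 0")
  assert_that(is_scalar_num(baseline_gain) && baseline_gain >= 0,
              "baseline_gain must be >= 0")
  assert_that(is_scalar_num(pickup_d0) && pickup_d0 > 0, "pickup_d0 must be > 0")
  assert_that(is_scalar_num(pickup_gamma) && pickup_gamma > 0,
              "pickup_gamma must be > 0")
  for (f in fascicles) {
    assert_that(sqrt(sum(f$center^2)) + f$radius <= nerve_radius + 1e-9,
                sprintf("fascicle '%s' does not fit inside the nerve", f$name))
  }
  rownames(gain_matrix) <- vapply(fascicles, `[[`, "", "name")
  structure(list(site = site, fascicles = fascicles, gain_matrix = gain_matrix,
                 baseline_gain = baseline_gain, pickup_d0 = pickup_d0,
                 pickup_gamma = pickup_gamma, nerve_radius = nerve_radius),
            class = "nerve_site_model")
}

#' @export
print.nerve_site_model <- function(x, ...) {
  cat(sprintf("<nerve_site_model '%s'> %d fascicles (%s), %d classes, d0=%.2g mm, gamma=%.2g\n",
              x$site, length(x$fascicles),
              paste(rownames(x$gain_matrix), collapse = ", "),
              ncol(x$gain_matrix), x$pickup_d0, x$pickup_gamma))
  invisible(x)
}

#' Default activation-gain matrix for a stimulus class set
#'
#' For a proprioceptive angle `theta` the matched fascicle (tibial for
#' negative angles, peroneal for positive) receives gain
#' `(|theta|/30) * 2` and the opposite fascicle `(|theta|/30) * 1`, encoding
#' both the magnitude effect (larger excursions raise MAV on all electrodes)
#' and the sign effect (the MAV ratio between electrodes differs for positive
#' versus negative angles). Nociception and touch classes drive the
#' sural/cutaneous fascicle with fixed gains: heel pinch 1.5, toe pinch 1.0,
#' heavy touch 0.5, light touch 0.3.
#'
#' @param classes a `stimulus_classes` data frame (see [stimulus_classes()]).
#' @return matrix fascicles x classes; row names are the fascicle names the
#'   matrix expects (`tibial`, `peroneal`, and `sural` when needed).
#' @export
default_gain_matrix <- function(classes) {
  classes <- validate_stimulus_classes(classes)
  needs_sural <- any(classes$modality %in% c("nociception", "touch"))
  fnames <- c("tibial", "peroneal", if (needs_sural) "sural")
  G <- matrix(0, nrow = length(fnames), ncol = nrow(classes),
              dimnames = list(fnames, classes$label))
  touch_gain <- c(heel_pinch = 1.5, toe_pinch = 1.0,
                  touch_heavy = 0.5, touch_light = 0.3)
  for (j in seq_len(nrow(classes))) {
    if (classes$modality[j] == "proprioception") {
      th <- classes$angle[j]
      base <- abs(th) / 30
      G["tibial", j]   <- base * (1 + as.numeric(th < 0))
      G["peroneal", j] <- base * (1 + as.numeric(th > 0))
    } else {
      lab <- classes$label[j]
      g <- if (lab %in% names(touch_gain)) touch_gain[[lab]] else 1.0
      G["sural", j] <- g
    }
  }
  G
}

#' Default nerve-site geometry for a stimulus class set
#'
#' Distal geometry separates the fascicles (tibial and peroneal centred at
#' (-0.3, 0) and (+0.3, 0) mm, sural at (0, -0.3)); proximal geometry places
#' the same fascicles almost concentrically ((-0.05, 0), (+0.05, 0),
#' (0, -0.05)), emulating the near-unifascicular proximal sciatic nerve.
#'
#' @inheritParams nerve_site_model
#' @param classes a `stimulus_classes` data frame; determines whether the
#'   sural fascicle is present and supplies the gain matrix via
#'   [default_gain_matrix()].
#' @param ... passed to [nerve_site_model()] (e.g. `baseline_gain`,
#'   `pickup_d0`).
#' @return a `nerve_site_model`.
#' @export
default_nerve_site <- function(site = c("distal", "proximal"), classes, ...) {
  site <- match.arg(site)
  G <- default_gain_matrix(classes)
  off <- if (site == "distal") 0.3 else 0.05
  fas <- list(fascicle_spec("tibial",   c(-off, 0), 0.15),
              fascicle_spec("peroneal", c(+off, 0), 0.15))
  if ("sural" %in% rownames(G)) {
    fas <- c(fas, list(fascicle_spec("sural", c(0, -off), 0.10)))
  }
  nerve_site_model(site = site, fascicles = fas, gain_matrix = G, ...)
}

#' Compute contact-by-fascicle pickup weights
#'
#' Evaluates the distance-based pickup model `w = (d0/(d0 + d))^gamma` for
#' every contact of a cuff layout against every fascicle of a site model.
#' Point contacts sit on the circle of radius `inner_diameter / 2` at their
#' angular position; ring contacts average the point formula over 36 equally
#' spaced angular positions (error < 0.1% versus a continuous ring at the
#' default geometry).
#'
#' @param layout a [build_cuff_layout()] result.
#' @param site a [nerve_site_model()].
#' @param n_ring_points number of quadrature points for ring contacts
#'   (default 36).
#' @return numeric matrix, channels x fascicles, all entries in (0, 1].
#' @export
compute_pickup_weights <- function(layout, site, n_ring_points = 36L) {
  validate_cuff_layout(layout)
  assert_that(inherits(site, "nerve_site_model"), "site must be a nerve_site_model")
  d0 <- site$pickup_d0
  gam <- site$pickup_gamma
  R <- layout$inner_diameter / 2
  centers <- t(vapply(site$fascicles, `[[`, numeric(2), "center"))
  nf <- nrow(centers)
  ct <- layout$contacts
  W <- matrix(NA_real_, nrow = nrow(ct), ncol = nf,
              dimnames = list(NULL, rownames(site$gain_matrix)))
  point_w <- function(theta_deg) {
    p <- c(R * cospi(theta_deg / 180), R * sinpi(theta_deg / 180))
    d <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
    (d0 / (d0 + d))^gam
  }
  for (i in seq_len(nrow(ct))) {
    if (ct$kind[i] == "point") {
      W[i, ] <- point_w(ct$angular_pos[i])
    } else {
      ang <- (seq_len(n_ring_points) - 1) * 360 / n_ring_points
      W[i, ] <- rowMeans(matrix(vapply(ang, point_w, numeric(nf)), nrow = nf))
    }
  }
  W
}
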