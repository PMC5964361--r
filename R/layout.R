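#' Construct a cuff electrode layout
#'
#' Builds one of the two canonical cuff geometries used throughout the
#' package:
#'
#' * `"cuff16"` — a concentric multi-contact cuff, 4.25 mm long with a 1.0 mm
#'   inner diameter, carrying four rings of four point contacts each
#'   (90 degrees apart within a ring; 16 channels in total);
#' * `"cuff3"` — a standard cuff, 4 mm long, 1.0 mm inner diameter, with
#'   three full circumferential ring contacts spaced 1 mm apart axially.
#'
#' Contacts are described in a data frame with one row per channel. Point
#' contacts have a meaningful `angular_pos`; ring contacts average the whole
#' circumference and carry `angular_pos = NA`. Axial ring positions within the
#' cuff are not critical to the cross-section pickup model and are placed at
#' the centres of equal axial subdivisions.
#'
#' @param name `"cuff16"` or `"cuff3"`.
#' @return an object of class `cuff_layout`: a list with `name`,
#'   `cuff_length` (mm), `inner_diameter` (mm) and `contacts`
#'   (data frame: `contact_id`, `kind`, `axial_pos`, `angular_pos`).
#' @examples
#' build_cuff_layout("cuff16")
#' @export
build_cuff_layout <- function(name = c("cuff16", "cuff3")) {
  valid <- c("cuff16", "cuff3")
  if (length(name) == 1L && !name %in% valid) {
    stop("unknown cuff layout '", name, "'; valid layouts: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  name <- match.arg(name)
  if (name == "cuff16") {
    len <- 4.25
    rings <- (seq_len(4) - 0.5) / 4 * len
    contacts <- data.frame(
      contact_id  = 0:15,
      kind        = "point",
      axial_pos   = rep(rings, each = 4),
      angular_pos = rep(c(0, 90, 180, 270), times = 4)
    )
    out <- list(name = name, cuff_length = len, inner_diameter = 1.0,
                contacts = contacts)
  } else {
    contacts <- data.frame(
      contact_id  = 0:2,
      kind        = "ring",
      axial_pos   = c(1.0, 2.0, 3.0),
      angular_pos = NA_real_
    )
    out <- list(name = name, cuff_length = 4.0, inner_diameter = 1.0,
                contacts = contacts)
  }
  class(out) <- "cuff_layout"
  validate_cuff_layout(out)
  out
}

validate_cuff_layout <- function(x) {
  assert_that(inherits(x, "cuff_layout"), "not a cuff_layout")
  ct <- x$contacts
  assert_that(!anyDuplicated(ct$contact_id), "contact ids must be unique")
  assert_that(all(ct$axial_pos >= 0 & ct$axial_pos <= x$cuff_length),
              "contact axial positions must lie within [0, cuff_length]")
  assert_that(all(ct$kind %in% c("point", "ring")),
              "contact kind must be 'point' or 'ring'")
  pt <- ct$kind == "point"
  assert_that(all(ct$angular_pos[pt] >= 0 & ct$angular_pos[pt] < 360),
              "point-contact angular positions must lie in [0, 360)")
  invisible(x)
}

#' Number of recording channels of a cuff layout
#' @param layout a `cuff_layout`.
#' @return integer channel count.
#' @export
n_channels <- function(layout) {
  validate_cuff_layout(layout)
  nrow(layout$contacts)
}

#' @export
print.cuff_layout <- function(x, ...) {
  cat(sprintf("<cuff_layout '%s'> %d contacts (%s), length %.2f mm, ID %.2f mm\n",
              x$name, nrow(x$contacts),
              paste(unique(x$contacts$kind), collapse = "+"),
              x$cuff_length, x$inner_diameter))
  invisible(x)
}
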