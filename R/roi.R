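# Landmark-anchored rectangular ROIs and per-ROI color statistics.
# Pixel coordinates are 0-based, row-major, origin top-left; rectangles are
# half-open [r0, r0 + h) x [c0, c0 + w).

#' Set of 68 facial landmarks
#'
#' Follows the standard 68-point facial annotation scheme (jaw 1--17, brows
#' 18--27, nose 28--36, eyes 37--48, mouth 49--68; 1-based indices).
#'
#' @param points data frame with columns `index`, `row`, `col` (0-based
#'   pixel coordinates), exactly 68 rows.
#' @param image_shape optional `c(rows, cols)`; when given, all points are
#'   checked to lie inside the image.
#' @param source `"detected"` or `"fixture"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, image_shape = NULL, source = "fixture") {
  points <- as.data.frame(points)
  if (!all(c("index", "row", "col") %in% names(points)))
    stop_structural("landmark points need columns index, row, col")
  if (nrow(points) != 68L)
    stop_validation("landmark set must contain exactly 68 points (got %d)", nrow(points))
  points <- points[order(points$index), c("index", "row", "col")]
  if (!identical(as.integer(points$index), 1:68))
    stop_validation("landmark indices must be 1..68")
  if (!is.null(image_shape)) {
    if (any(points$row < 0) || any(points$col < 0) ||
        any(points$row >= image_shape[1]) || any(points$col >= image_shape[2]))
      stop_validation("landmark(s) outside image bounds %d x %d",
                      image_shape[1], image_shape[2])
  }
  structure(list(points = points, source = source, image_shape = image_shape),
            class = "landmark_set")
}

#' Locate facial landmarks with a pluggable backend
#'
#' The detector itself is pluggable: `backend` is either a function
#' `image -> landmark_set` (e.g. wrapping an external detector) or a stored
#' [landmark_set()] fixture which is returned verbatim after bounds
#' validation against the image. The fixture backend is deterministic.
#'
#' @param image a [lab_image()], matrix, or `c(rows, cols)` shape.
#' @param backend a function or a [landmark_set()].
#' @return A [landmark_set()] with all 68 points inside the image.
#' @export
detect_landmarks <- function(image, backend) {
  shape <- image_shape_of(image)
  if (any(shape < 1)) stop_validation("image is empty")
  lm <- if (is.function(backend)) backend(image)
  else if (inherits(backend, "landmark_set")) backend
  else stop_structural("backend must be a function or a landmark_set")
  if (!inherits(lm, "landmark_set"))
    stop_structural("backend did not return a landmark_set")
  landmark_set(lm$points, image_shape = shape, source = lm$source)
}

image_shape_of <- function(image) {
  if (inherits(image, "lab_image")) image$shape
  else if (inherits(image, "reflectance_cube")) dim(image$values)[2:3]
  else if (is.matrix(image)) dim(image)
  else if (is.numeric(image) && length(image) == 2) as.integer(image)
  else stop_structural("cannot determine image shape from a %s", class(image)[1])
}

#' Landmark-anchored ROI definition
#'
#' The anchor is the centroid of a configurable triple of landmark indices;
#' the defaults place a 75 x 75 pixel square on each cheek. Which landmarks
#' anchor the cheek is a protocol choice recorded in output provenance.
#'
#' @param name ROI name, e.g. `"Right_Cheek"`.
#' @param anchor_indices landmark indices (1-based) whose centroid anchors
#'   the ROI center.
#' @param size_px `c(height, width)` in pixels, default `c(75, 75)`.
#' @return An object of class `roi_definition`.
#' @export
roi_definition <- function(name, anchor_indices, size_px = c(75, 75)) {
  if (any(size_px < 1)) stop_validation("ROI size must be positive")
  if (any(anchor_indices < 1 | anchor_indices > 68))
    stop_validation("anchor indices must be in 1..68")
  structure(list(name = name, anchor_indices = as.integer(anchor_indices),
                 size_px = as.integer(size_px)),
            class = "roi_definition")
}

#' @rdname roi_definition
#' @param size_px `c(height, width)` in pixels.
#' @export
right_cheek_roi <- function(size_px = c(75, 75)) {
  roi_definition("Right_Cheek", c(3L, 32L, 37L), size_px)
}

#' @rdname roi_definition
#' @export
left_cheek_roi <- function(size_px = c(75, 75)) {
  roi_definition("Left_Cheek", c(15L, 36L, 46L), size_px)
}

#' Resolve a ROI definition to a pixel rectangle
#'
#' Centers the rectangle on the anchor (rounded centroid of the anchor
#' landmarks), placing the top-left corner at `anchor - floor(size / 2)`.
#' A rectangle that would cross the image edge is shifted inward (logged),
#' never truncated.
#'
#' @param landmarks a [landmark_set()].
#' @param definition a [roi_definition()].
#' @param image_shape `c(rows, cols)`; defaults to the landmark set's shape.
#' @return A `roi_rect`: list with `name`, `r0`, `c0`, `h`, `w` (half-open
#'   `[r0, r0 + h) x [c0, c0 + w)`, 0-based).
#' @export
resolve_roi <- function(landmarks, definition, image_shape = NULL) {
  if (is.null(image_shape)) image_shape <- landmarks$image_shape
  if (is.null(image_shape)) stop_validation("image_shape is required")
  h <- definition$size_px[1]; w <- definition$size_px[2]
  if (h > image_shape[1] || w > image_shape[2])
    stop_validation("image %d x %d is smaller than the %d x %d ROI",
                    image_shape[1], image_shape[2], h, w)
  pts <- landmarks$points[landmarks$points$index %in% definition$anchor_indices, ]
  anchor <- round(c(mean(pts$row), mean(pts$col)))
  r0 <- anchor[1] - floor(h / 2)
  c0 <- anchor[2] - floor(w / 2)
  r0c <- min(max(r0, 0), image_shape[1] - h)
  c0c <- min(max(c0, 0), image_shape[2] - w)
  if (r0c != r0 || c0c != c0)
    hsi_log("resolve_roi: %s shifted inward by (%d, %d) px at the image edge",
            definition$name, r0c - r0, c0c - c0)
  structure(list(name = definition$name, r0 = as.integer(r0c),
                 c0 = as.integer(c0c), h = as.integer(h), w = as.integer(w),
                 anchor = as.integer(anchor),
                 anchor_indices = definition$anchor_indices),
            class = "roi_rect")
}

#' Per-ROI color statistics
#'
#' Channel means, sample SDs and histograms of the L*, a*, b* values inside
#' a rectangle. Histogram bin edges can be supplied so that before/after
#' pairs share a scale; by default 64 uniform bins span each channel's range.
#'
#' @param lab a [lab_image()].
#' @param rect a `roi_rect` from [resolve_roi()].
#' @param breaks optional named list (`L`, `a`, `b`) of bin edge vectors.
#' @param n_bins number of uniform bins when `breaks` is `NULL`.
#' @return An object of class `roi_stats` with fields `name`, `n_pixels`,
#'   and per-channel `mean`, `sd`, `hist` (edges + counts).
#' @export
extract_roi_stats <- function(lab, rect, breaks = NULL, n_bins = 64) {
  shp <- lab$shape
  if (rect$r0 < 0 || rect$c0 < 0 || rect$r0 + rect$h > shp[1] ||
      rect$c0 + rect$w > shp[2])
    stop_validation("ROI [%d,%d) x [%d,%d) lies outside the %d x %d image",
                    rect$r0, rect$r0 + rect$h, rect$c0, rect$c0 + rect$w,
                    shp[1], shp[2])
  rows <- (rect$r0 + 1):(rect$r0 + rect$h)
  cols <- (rect$c0 + 1):(rect$c0 + rect$w)
  chans <- list(L = lab$L[rows, cols], a = lab$a[rows, cols], b = lab$b[rows, cols])
  out <- lapply(names(chans), function(ch) {
    v <- as.vector(chans[[ch]])
    edges <- if (!is.null(breaks)) breaks[[ch]] else {
      rng <- range(v)
      if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
      seq(rng[1], rng[2], length.out = n_bins + 1)
    }
    counts <- graphics::hist(pmin(pmax(v, edges[1]), edges[length(edges)]),
                             breaks = edges, plot = FALSE)$counts
    list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
         hist = list(edges = edges, counts = counts))
  })
  names(out) <- names(chans)
  structure(list(name = rect$name, n_pixels = rect$h * rect$w,
                 size_px = c(rect$h, rect$w), channels = out),
            class = "roi_stats")
}

#' Shared histogram edges for a before/after pair of ROIs
#'
#' @param lab_before,lab_after [lab_image()]s.
#' @param rect_before,rect_after `roi_rect`s.
#' @param n_bins number of uniform bins.
#' @return Named list of bin edge vectors spanning the pooled range.
#' @export
shared_breaks <- function(lab_before, rect_before, lab_after, rect_after,
                          n_bins = 64) {
  grab <- function(lab, rect, ch) {
    rows <- (rect$r0 + 1):(rect$r0 + rect$h)
    cols <- (rect$c0 + 1):(rect$c0 + rect$w)
    as.vector(lab[[ch]][rows, cols])
  }
  out <- lapply(c(L = "L", a = "a", b = "b"), function(ch) {
    rng <- range(c(grab(lab_before, rect_before, ch),
                   grab(lab_after, rect_after, ch)))
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = n_bins + 1)
  })
  out
}

#' Before/after color change of a ROI
#'
#' The product effect for one session: per-channel difference of ROI means
#' between the before (`T_0`) and immediately-after (`T_imm`) images, and
#' the CIE76 color difference of the two mean colors.
#'
#' @param before,after [extract_roi_stats()] results for the same ROI.
#' @return List with `dL`, `da`, `db` (after minus before) and `dE`.
#' @export
roi_difference <- function(before, after) {
  if (!identical(before$name, after$name) ||
      !identical(before$size_px, after$size_px))
    stop_validation("before/after ROI identity mismatch (%s %s vs %s %s)",
                    before$name, paste(before$size_px, collapse = "x"),
                    after$name, paste(after$size_px, collapse = "x"))
  m0 <- c(before$channels$L$mean, before$channels$a$mean, before$channels$b$mean)
  m1 <- c(after$channels$L$mean, after$channels$a$mean, after$channels$b$mean)
  list(roi = before$name, dL = m1[1] - m0[1], da = m1[2] - m0[2],
       db = m1[3] - m0[3], dE = delta_e(m0, m1))
}

#' Physical pixel pitch of a ROI
#'
#' @param physical_size_mm physical extent in millimetres.
#' @param size_px extent in pixels.
#' @return Pixel pitch in micrometres: `1000 * mm / pixels`. A 12 mm ROI
#'   spanning 75 pixels gives 160 um.
#' @export
pixel_pitch <- function(physical_size_mm, size_px) {
  if (any(size_px <= 0)) stop_validation("pixel count must be positive")
  if (any(physical_size_mm <= 0)) stop_validation("physical size must be positive")
  1000 * physical_size_mm / size_px
}
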