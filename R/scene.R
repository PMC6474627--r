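#' Construct a multi-channel scene
#'
#' A scene holds the co-registered channels of one microscope field as
#' named 2-D numeric matrices (or 3-D z-stacks), keyed by channel role.
#' Recognised role prefixes are `dapi`, `brightfield`, `fish:<gene>`,
#' `intron:<gene>` and `protein:<gene>`. All channels must share the
#' same spatial dimensions and contain non-negative finite intensities.
#' Pixel indices are 1-based (row, col) with pixel centers at integer
#' coordinates.
#'
#' @param channels Named list of numeric matrices (or 3-D arrays) keyed
#'   by role, e.g. `list(dapi = m1, "fish:IL1B" = m2)`.
#' @param pixel_size Optional pixel pitch in micrometres per pixel.
#' @param source_id Identifier string recorded in downstream tables.
#' @return An object of class `smfish_scene`.
#' @export
scene <- function(channels, pixel_size = NULL, source_id = "scene") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a fully named list of arrays", call. = FALSE)
  dims <- lapply(channels, function(ch) dim(ch)[1:2])
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share identical spatial dimensions",
         call. = FALSE)
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch) || !(length(dim(ch)) %in% c(2L, 3L)))
      stop("channel '", nm, "' must be a 2-D matrix or 3-D array",
           call. = FALSE)
    if (anyNA(ch) || any(!is.finite(ch)) || any(ch < 0))
      stop("channel '", nm, "' has negative or non-finite intensities",
           call. = FALSE)
  }
  z <- max(vapply(channels, function(ch)
    if (length(dim(ch)) == 3L) dim(ch)[3] else 1L, integer(1)))
  structure(
    list(channels = channels, pixel_size = pixel_size,
         z_planes = z, source_id = source_id),
    class = "smfish_scene")
}

#' @export
print.smfish_scene <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat("<smfish_scene> ", x$source_id, ": ", d[1], "x", d[2],
      " px, ", length(x$channels), " channel(s) [",
      paste(names(x$channels), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Fetch one channel of a scene (NULL if absent)
#' @param x An `smfish_scene`.
#' @param role Channel role string, e.g. `"fish:IL1B"`.
#' @export
scene_channel <- function(x, role) {
  stopifnot(inherits(x, "smfish_scene"))
  x$channels[[role]]
}

#' Read a multi-page grayscale TIFF into a scene
#'
#' Each page of the TIFF is mapped to a channel role through
#' `channel_role_map`, a named list/vector `role = page index`.
#'
#' @param path Path to a single- or multi-page grayscale TIFF.
#' @param channel_role_map Named vector mapping roles to page indices
#'   (1-based), e.g. `c(dapi = 1, brightfield = 2, "fish:IL1B" = 3)`.
#' @param pixel_size,source_id Passed through to [scene()]. `source_id`
#'   defaults to the file name.
#' @return An `smfish_scene`.
#' @export
read_scene <- function(path, channel_role_map, pixel_size = NULL,
                       source_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages)
    if (length(dim(p)) > 2L && dim(p)[3] > 1L)
      stop("non-grayscale TIFF page (", dim(p)[3], " samples/pixel)",
           call. = FALSE)
  map <- unlist(channel_role_map)
  if (is.null(names(map)) || any(!nzchar(names(map))))
    stop("channel_role_map must be named by role", call. = FALSE)
  if (any(map < 1 | map > length(pages)))
    stop("channel_role_map references page(s) ",
         paste(map[map < 1 | map > length(pages)], collapse = ", "),
         " but the TIFF has ", length(pages), " page(s)", call. = FALSE)
  chans <- lapply(map, function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3L) m <- m[, , 1]
    storage.mode(m) <- "double"
    m
  })
  names(chans) <- names(map)
  scene(chans, pixel_size = pixel_size,
        source_id = source_id %||% basename(path))
}

#' Write a scene to a multi-page grayscale TIFF
#'
#' Channels are written as camera-native 16-bit integer pages in the
#' order given by `roles` (default: all channels in scene order).
#' Intensities are rounded to integers and clipped at 65535; a scene
#' whose intensities are already integers in range (as all simulated
#' and camera scenes are) round-trips bit-identically through
#' [read_scene()].
#'
#' @param x An `smfish_scene`.
#' @param path Output TIFF path.
#' @param roles Character vector of channel roles to write.
#' @return Invisibly, the named page map usable as `channel_role_map`.
#' @export
write_scene <- function(x, path, roles = names(x$channels)) {
  stopifnot(inherits(x, "smfish_scene"))
  pages <- lapply(roles, function(r) {
    ch <- scene_channel(x, r)
    if (is.null(ch)) stop("scene has no channel '", r, "'", call. = FALSE)
    if (length(dim(ch)) == 3L) ch <- max_project(ch)
    pmin(round(ch), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(setNames(seq_along(roles), roles))
}

#' Maximum-intensity projection of a z-stack
#'
#' Reduces a 3-D array to a single analysis plane by taking the
#' per-pixel maximum over z. A 2-D input (or single-plane stack) is
#' returned unchanged as a matrix.
#'
#' @param stack 2-D matrix or 3-D array with at least one z-plane.
#' @return A 2-D matrix.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (is.null(d) || length(d) != 3L || d[3] < 1L)
    stop("stack must be a 2-D matrix or 3-D array with >= 1 z-plane",
         call. = FALSE)
  if (d[3] == 1L) return(stack[, , 1])
  apply(stack, c(1, 2), max)
}

#' Project every z-stacked channel of a scene
#' @param x An `smfish_scene`.
#' @return The scene with every channel reduced to 2-D via [max_project()].
#' @export
project_scene <- function(x) {
  stopifnot(inherits(x, "smfish_scene"))
  x$channels <- lapply(x$channels, max_project)
  x$z_planes <- 1L
  x
}
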