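#' @include AllClasses.R
NULL

# The acquisition container is a hierarchical array file: a named tree of
# datasets addressed by slash-paths, serialized with R's native
# serialization.  Dataset paths (bit-exact):
#   encoded containers: /encoded/complex, /encoded/moments,
#     /meta/{venc,frame_ms,pixel_mm,fov_rotation_deg,n_frames_cycle}
#   velocity containers: /velocity, /magnitude, /wrapped (optional),
#     /meta/{venc,frame_ms,pixel_mm,n_frames_cycle}

.containerGet <- function(tree, path) {
  parts <- strsplit(sub("^/", "", path), "/")[[1]]
  node <- tree
  for (p in parts) {
    if (!is.list(node) || is.null(node[[p]]))
      stop("missing ", path)
    node <- node[[p]]
  }
  node
}

#' Write an acquisition container
#'
#' Serializes an [EncodedAcquisition-class] or [VelocityCine-class] to the
#' package's hierarchical array-container format (see the container schema
#' in the package vignette).  Round-trips are bit-exact.
#'
#' @param x the object to write
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeAcquisition <- function(x, path) {
  tree <- if (methods::is(x, "EncodedAcquisition")) {
    list(encoded = list(complex = x@data, moments = x@moments),
         meta = list(venc = x@vencCmS, frame_ms = x@frameMs,
                     pixel_mm = x@pixelMm,
                     fov_rotation_deg = x@fovRotationDeg,
                     n_frames_cycle = x@nFramesCycle))
  } else if (methods::is(x, "VelocityCine")) {
    list(velocity = x@velocity, magnitude = x@magnitude, wrapped = x@wrapped,
         meta = list(venc = x@vencCmS, frame_ms = x@frameMs,
                     pixel_mm = x@pixelMm,
                     n_frames_cycle = x@nFramesCycle))
  } else stop("cannot write objects of class ", class(x))
  saveRDS(tree, path)
  invisible(path)
}

#' Read an acquisition container
#'
#' Reads and validates a container written by [writeAcquisition()] (or the
#' `tpm phantom` command).  Containers holding `/encoded/complex` yield an
#' [EncodedAcquisition-class]; containers holding `/velocity` yield a
#' [VelocityCine-class] (the reconstruction stage is then skipped by the
#' pipeline).  A missing required dataset raises an error naming its path.
#'
#' @param path container file path
#' @return an [EncodedAcquisition-class] or [VelocityCine-class]
#' @export
readAcquisition <- function(path) {
  tree <- readRDS(path)
  if (!is.null(tree$encoded)) {
    cx <- .containerGet(tree, "/encoded/complex")
    mom <- .containerGet(tree, "/encoded/moments")
    methods::new("EncodedAcquisition", data = cx, moments = mom,
                 vencCmS = .containerGet(tree, "/meta/venc"),
                 frameMs = .containerGet(tree, "/meta/frame_ms"),
                 pixelMm = .containerGet(tree, "/meta/pixel_mm"),
                 fovRotationDeg =
                   .containerGet(tree, "/meta/fov_rotation_deg"),
                 nFramesCycle =
                   as.integer(.containerGet(tree, "/meta/n_frames_cycle")))
  } else if (!is.null(tree$velocity)) {
    vel <- .containerGet(tree, "/velocity")
    mag <- .containerGet(tree, "/magnitude")
    wrapped <- tree$wrapped
    if (is.null(wrapped)) wrapped <- array(FALSE, dim(mag))
    methods::new("VelocityCine", velocity = vel, magnitude = mag,
                 wrapped = wrapped,
                 vencCmS = .containerGet(tree, "/meta/venc"),
                 frameMs = .containerGet(tree, "/meta/frame_ms"),
                 pixelMm = .containerGet(tree, "/meta/pixel_mm"),
                 nFramesCycle =
                   as.integer(.containerGet(tree, "/meta/n_frames_cycle")))
  } else stop("missing /encoded/complex (or /velocity)")
}

#' Write contour annotations
#'
#' Plain-text annotation format: a key-value header (`t_last_diastole`, two
#' `papillary` lines) followed by polygon blocks introduced by `>epi
#' frame=N`, `>endo frame=N`, `>foldover` or `>static` headers, one `x_mm
#' y_mm` vertex per line, blank-line separated.
#'
#' @param contours a [ContourSet-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeAnnotations <- function(contours, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmtPoly <- function(p) apply(p, 1, function(v)
    sprintf("%.17g %.17g", v[1], v[2]))
  lines <- c("# tpmcmr annotations v1",
             sprintf("t_last_diastole: %d", contours@tLastDiastole),
             sprintf("papillary: %.17g %.17g", contours@papillary[, 1],
                     contours@papillary[, 2]),
             "")
  for (i in seq_along(contours@keyFrames)) {
    lines <- c(lines, sprintf(">epi frame=%d", contours@keyFrames[i]),
               fmtPoly(contours@epi[[i]]), "",
               sprintf(">endo frame=%d", contours@keyFrames[i]),
               fmtPoly(contours@endo[[i]]), "")
  }
  for (p in contours@foldover)
    lines <- c(lines, ">foldover", fmtPoly(p), "")
  for (p in contours@staticRegions)
    lines <- c(lines, ">static", fmtPoly(p), "")
  writeLines(lines, con)
  invisible(path)
}

#' Read contour annotations
#'
#' Parses the plain-text annotation format of [writeAnnotations()].  The
#' end-diastolic frame (`t_last_diastole`) and the papillary landmarks are
#' required human inputs; fold-over and static regions may be absent.
#'
#' @param path annotation file path
#' @return a [ContourSet-class]
#' @export
readAnnotations <- function(path) {
  raw <- readLines(path)
  raw <- trimws(raw)
  raw <- raw[!grepl("^#", raw)]
  headerEnd <- which(grepl("^>", raw))[1]
  if (is.na(headerEnd)) stop("no polygon blocks found in ", path)
  header <- raw[seq_len(headerEnd - 1)]
  header <- header[nzchar(header)]
  getVals <- function(key) {
    sel <- grepl(paste0("^", key, ":"), header)
    sub(paste0("^", key, ":\\s*"), "", header[sel])
  }
  tld <- getVals("t_last_diastole")
  if (length(tld) != 1)
    stop("missing t_last_diastole (required annotation input)")
  papLines <- getVals("papillary")
  if (length(papLines) != 2)
    stop("exactly two papillary landmarks are required")
  pap <- do.call(rbind, lapply(strsplit(papLines, "\\s+"), as.numeric))
  body <- raw[headerEnd:length(raw)]
  starts <- which(grepl("^>", body))
  ends <- c(starts[-1] - 1, length(body))
  epi <- list(); endo <- list(); fold <- list(); statics <- list()
  epiFrames <- integer(); endoFrames <- integer()
  for (i in seq_along(starts)) {
    head <- body[starts[i]]
    verts <- body[(starts[i] + 1):ends[i]]
    verts <- verts[nzchar(verts)]
    poly <- if (length(verts))
      do.call(rbind, lapply(strsplit(verts, "\\s+"), as.numeric))
    else matrix(numeric(), 0, 2)
    if (nrow(poly) < 3)
      stop("polygon with fewer than 3 vertices in block '", head, "'")
    if (grepl("^>epi", head)) {
      epi[[length(epi) + 1]] <- poly
      epiFrames <- c(epiFrames,
                     as.integer(sub(".*frame=(\\d+).*", "\\1", head)))
    } else if (grepl("^>endo", head)) {
      endo[[length(endo) + 1]] <- poly
      endoFrames <- c(endoFrames,
                      as.integer(sub(".*frame=(\\d+).*", "\\1", head)))
    } else if (grepl("^>foldover", head)) {
      fold[[length(fold) + 1]] <- poly
    } else if (grepl("^>static", head)) {
      statics[[length(statics) + 1]] <- poly
    } else stop("unknown annotation block '", head, "'")
  }
  if (!identical(epiFrames, endoFrames))
    stop("epi and endo key frames disagree")
  methods::new("ContourSet", keyFrames = epiFrames, epi = epi, endo = endo,
               papillary = pap, foldover = fold, staticRegions = statics,
               tLastDiastole = as.integer(tld))
}

# rasterize a list of polygons onto the pixel grid -> logical (ny, nx)
.rasterizePolys <- function(polys, gridSize, pixelMm) {
  n <- gridSize
  co <- .pixelCoords(n, pixelMm)
  px <- rep(co, each = n)
  py <- rep(co, times = n)
  matrix(.inAnyPoly(px, py, polys), n, n)
}

#' Rasterize annotation regions onto the pixel grid
#'
#' Pixel-centre membership mask for a list of polygons (for example the
#' static-tissue or fold-over regions of a [ContourSet-class]), on the
#' package's grid convention.
#'
#' @param polys list of polygon matrices (mm coordinates)
#' @param gridSize image matrix size (pixels)
#' @param pixelMm pixel size (mm)
#' @return logical (y, x) matrix
#' @export
rasterizeRegions <- function(polys, gridSize, pixelMm) {
  .rasterizePolys(polys, gridSize, pixelMm)
}
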