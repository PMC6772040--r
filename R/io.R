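# ---------------------------------------------------------------------------
# NIfTI input/output through RNifti. Scalar and label volumes are 3-D files;
# multi-channel images are 4-D with one volume per channel; displacement
# fields are 4-D with trailing dimension 3 and NIfTI intent code 1007
# (vector), which disambiguates them from 3-channel images.
# ---------------------------------------------------------------------------

NIFTI_INTENT_VECTOR <- 1007L

nifti_meta <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  pd <- hdr$pixdim[2:4]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("malformed NIfTI header: non-positive spacing (pixdim)",
         call. = FALSE)
  xf <- RNifti::xform(img)
  list(spacing = pd, origin = as.numeric(xf[1:3, 4]),
       intent = hdr$intent_code)
}

as_nifti_obj <- function(arr, spacing, origin, intent = 0L) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(spacing, rep(1, nd - 3L))
  m <- diag(4)
  m[1, 1] <- spacing[1]; m[2, 2] <- spacing[2]; m[3, 3] <- spacing[3]
  m[1:3, 4] <- origin
  img <- RNifti::`qform<-`(img, value = structure(m, code = 2L))
  img$intent_code <- as.integer(intent)
  img
}

#' Write a volume object to a NIfTI file
#'
#' Spacing and origin are stored in the header (qform); displacement fields
#' carry the NIfTI vector intent code. A write-then-read round trip
#' preserves data and grid metadata to float precision.
#'
#' @param x An `image_volume`, `label_volume`, `displacement_field` or
#'   `jacobian_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "image_volume")) {
    ch <- x$channels
    arr <- if (length(ch) == 1L) ch[[1L]] else {
      a <- array(0, c(vol_shape(x), length(ch)))
      for (k in seq_along(ch)) a[, , , k] <- ch[[k]]
      a
    }
    img <- as_nifti_obj(arr, x$spacing, x$origin)
    attr(img, "channel_names") <- names(ch)
  } else if (inherits(x, "label_volume")) {
    img <- as_nifti_obj(x$labels, x$spacing, x$origin)
  } else if (inherits(x, "displacement_field")) {
    img <- as_nifti_obj(x$vectors, x$spacing, x$origin,
                        intent = NIFTI_INTENT_VECTOR)
  } else if (inherits(x, "jacobian_map")) {
    img <- as_nifti_obj(x$values, x$spacing, x$origin)
  } else stop("cannot write this type as NIfTI", call. = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume object from a NIfTI file
#'
#' @param path NIfTI file path.
#' @param what One of `"auto"`, `"image"`, `"label"`, `"field"`,
#'   `"jacobian"`. With `"auto"`, a 4-D file with trailing dimension 3 and
#'   vector intent is read as a `displacement_field`, any other 4-D file as
#'   a multi-channel `image_volume`, and a 3-D file as a single-channel
#'   `image_volume`.
#' @param channels Optional channel names for multi-channel images.
#' @return The corresponding volume object.
#' @export
read_volume <- function(path, what = c("auto", "image", "label", "field",
                                       "jacobian"),
                        channels = NULL) {
  what <- match.arg(what)
  img <- RNifti::readNifti(path)
  meta <- nifti_meta(img)
  arr <- array(as.vector(as.array(img)), dim(img))  # plain array, no header attrs
  if (any(!is.finite(arr)))
    stop("NIfTI payload contains non-finite values: ", path, call. = FALSE)
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L))
    stop("expected a 3-D or 4-D NIfTI file, got ", nd, "-D: ", path,
         call. = FALSE)
  is_vec <- nd == 4L && dim(arr)[4L] == 3L &&
    identical(as.integer(meta$intent), NIFTI_INTENT_VECTOR)
  if (what == "auto")
    what <- if (nd == 3L) "image" else if (is_vec) "field" else "image"
  switch(what,
    field = {
      if (nd != 4L || dim(arr)[4L] != 3L)
        stop("not a displacement field (need 4-D with trailing dimension 3): ",
             path, call. = FALSE)
      displacement_field(arr, meta$spacing, meta$origin)
    },
    label = {
      if (nd != 3L)
        stop("label volumes must be 3-D: ", path, call. = FALSE)
      label_volume(arr, meta$spacing, meta$origin)
    },
    jacobian = {
      if (nd != 3L)
        stop("Jacobian maps must be 3-D: ", path, call. = FALSE)
      jacobian_map(arr, meta$spacing, meta$origin)
    },
    image = {
      if (nd == 3L) {
        nm <- channels %||% "value"
        image_volume(setNames(list(arr), nm[1L]), meta$spacing, meta$origin)
      } else {
        k <- dim(arr)[4L]
        nm <- channels %||% paste0("ch", seq_len(k))
        if (length(nm) != k)
          stop("need ", k, " channel names", call. = FALSE)
        ch <- lapply(seq_len(k), function(q) array(arr[, , , q],
                                                   dim(arr)[1:3]))
        image_volume(setNames(ch, nm), meta$spacing, meta$origin)
      }
    })
}

#' Read a cohort metadata table
#'
#' CSV with columns `subject_id`, `fat_mass_kg`, `height_cm` and optional
#' file-reference columns `image`, `mask`, `labels`; column names are
#' normalized to `subject_id`, `fat_mass`, `height`.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ren <- c(fat_mass_kg = "fat_mass", height_cm = "height")
  for (old in names(ren))
    if (old %in% names(df)) names(df)[names(df) == old] <- ren[[old]]
  need <- c("subject_id", "fat_mass", "height")
  if (!all(need %in% names(df)))
    stop("cohort table must have columns subject_id, fat_mass_kg, height_cm",
         call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Write a metrics or convergence report as JSON
#'
#' @param report A list (nested lists/vectors of numbers and strings).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
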