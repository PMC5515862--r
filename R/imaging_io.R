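#' Load a co-registered pre/post-contrast volume pair
#'
#' Reads two NIfTI volumes, checks grid compatibility (equal shapes and
#' voxel spacings) and returns them as plain arrays with the slice axis
#' last. Registration is assumed done upstream; only grid equality is
#' enforced.
#'
#' @param path_pre,path_post Paths to NIfTI files (`.nii` or `.nii.gz`).
#' @param patient_id Optional identifier carried through.
#' @return A list of class `volume_pair`: `pre`, `post` (3D arrays),
#'   `spacing` (voxel dimensions), `patient_id`.
#' @export
load_volume_pair <- function(path_pre, path_post, patient_id = NA_character_) {
  for (p in c(path_pre, path_post))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  img_pre <- RNifti::readNifti(path_pre)
  img_post <- RNifti::readNifti(path_post)
  pre <- as.array(img_pre)
  attributes(pre) <- list(dim = dim(pre))
  post <- as.array(img_post)
  attributes(post) <- list(dim = dim(post))
  if (!identical(dim(pre), dim(post)))
    stop("alignment error: pre (", paste(dim(pre), collapse = "x"),
         ") and post (", paste(dim(post), collapse = "x"),
         ") volumes differ in shape", call. = FALSE)
  sp_pre <- RNifti::pixdim(img_pre)
  sp_post <- RNifti::pixdim(img_post)
  if (max(abs(sp_pre - sp_post)) > 1e-6)
    stop("alignment error: voxel spacings differ between pre and post volumes",
         call. = FALSE)
  if (any(!is.finite(pre)) || any(!is.finite(post)))
    stop("data error: non-finite voxel values", call. = FALSE)
  structure(list(pre = pre, post = post, spacing = sp_pre,
                 patient_id = patient_id), class = "volume_pair")
}

#' Load tissue masks and resolve overlaps
#'
#' Reads binary masks (thresholded at 0.5), verifies they match the
#' reference grid, and resolves any overlapping voxels by pathological
#' specificity: stroke > WMH > DGM > CSF > NAWM. The number of reassigned
#' voxels is reported via the `overlap_resolved` attribute and a warning;
#' resolution is idempotent. A requested tissue whose mask is empty (or
#' whose file is missing) is skipped with a warning and flagged absent.
#'
#' @param paths Named character vector/list, tissue -> NIfTI path. Names
#'   must be among NAWM, DGM, WMH, CSF, stroke.
#' @param reference A `volume_pair` (or 3D array) defining the grid.
#' @return Named list of logical 3D arrays with attributes
#'   `overlap_resolved` (count) and `absent` (character vector).
#' @export
load_masks <- function(paths, reference) {
  ref_dim <- if (inherits(reference, "volume_pair")) dim(reference$pre) else dim(reference)
  bad <- setdiff(names(paths), TISSUES)
  if (length(bad)) stop("unknown tissue name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  masks <- list()
  absent <- character(0)
  for (t in names(paths)) {
    if (!file.exists(paths[[t]])) {
      warning("mask file missing for ", t, "; tissue flagged absent")
      absent <- c(absent, t)
      next
    }
    m <- as.array(RNifti::readNifti(paths[[t]])) > 0.5
    if (!identical(dim(m), ref_dim))
      stop("alignment error: mask for ", t, " does not match reference grid",
           call. = FALSE)
    if (!any(m)) {
      warning("empty mask for ", t, "; tissue flagged absent")
      absent <- c(absent, t)
      next
    }
    masks[[t]] <- m
  }
  res <- resolve_mask_overlaps(masks)
  attr(res, "absent") <- absent
  res
}

#' Resolve overlapping tissue masks by priority
#'
#' Assigns each voxel claimed by several masks to the highest-priority
#' tissue (stroke > WMH > DGM > CSF > NAWM). Order-independent given the
#' fixed priority list and idempotent.
#'
#' @param masks Named list of logical arrays.
#' @return The disjoint masks with attribute `overlap_resolved`.
#' @export
resolve_mask_overlaps <- function(masks) {
  present <- intersect(MASK_PRIORITY, names(masks))
  claimed <- NULL
  n_resolved <- 0L
  out <- masks
  for (t in present) {
    m <- masks[[t]]
    if (is.null(claimed)) claimed <- array(FALSE, dim(m))
    overlap <- m & claimed
    n_overlap <- sum(overlap)
    if (n_overlap > 0) {
      n_resolved <- n_resolved + n_overlap
      m <- m & !claimed
    }
    out[[t]] <- m
    claimed <- claimed | m
  }
  if (n_resolved > 0)
    warning(n_resolved, " overlapping mask voxel(s) reassigned by priority")
  attr(out, "overlap_resolved") <- n_resolved
  out
}

#' Extract a masked region from a volume
#'
#' Returns the in-mask voxel values together with the mask itself so that
#' spatial neighbor queries (co-occurrence pairs) remain possible.
#'
#' @param volume 3D numeric array.
#' @param mask 3D logical array of the same shape.
#' @return A list of class `masked_region`: `values`, `mask`, `dim`.
#' @export
extract_region <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask)))
    stop("shape mismatch between volume and mask", call. = FALSE)
  if (!any(mask)) stop("empty-region error: mask selects no voxels", call. = FALSE)
  structure(list(values = volume[mask], mask = mask, dim = dim(volume)),
            class = "masked_region")
}
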