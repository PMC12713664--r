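# Plain-text dataset IO, results export, and optional neuroimaging adapters.
#
# Native formats are TSV throughout so datasets are portable and diffable:
#   coords.tsv       vertex_id  x  y  [z]
#   parcels.tsv      vertex_id  parcel_id
#   sub-<id>.tsv     T rows x V columns of BOLD values (header = vertex ids)
#   events_<k>.tsv   onset  duration  amplitude   (FSL 3-column style)
# Vertex ids are 0-based integers; parcel ids are opaque strings.

#' Write a dataset directory
#'
#' @param dir Output directory (created if needed).
#' @param coords `V x d` coordinates.
#' @param parcels Length-`V` parcel labels.
#' @param Y_list Named (or unnamed) list of `T x V` subject matrices.
#' @param stims List of [stim_train()]s.
#' @param TR Repetition time in seconds (stored in `meta.yaml`).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dir, coords, parcels, Y_list, stims = NULL, TR = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coords <- as.matrix(coords)
  V <- nrow(coords)
  vid <- 0:(V - 1L)
  cdf <- data.frame(vertex_id = vid, coords)
  colnames(cdf) <- c("vertex_id", c("x", "y", "z")[seq_len(ncol(coords))])
  data.table::fwrite(cdf, file.path(dir, "coords.tsv"), sep = "\t")
  data.table::fwrite(data.frame(vertex_id = vid,
                                parcel_id = as.character(parcels)),
                     file.path(dir, "parcels.tsv"), sep = "\t")
  ids <- names(Y_list) %||% sprintf("%02d", seq_along(Y_list))
  for (i in seq_along(Y_list)) {
    m <- as.data.frame(as.matrix(Y_list[[i]]))
    colnames(m) <- sprintf("v%d", vid)
    data.table::fwrite(m, file.path(dir, sprintf("sub-%s.tsv", ids[i])),
                       sep = "\t")
  }
  if (!is.null(stims)) {
    for (st in stims)
      data.table::fwrite(
        data.frame(st$onsets, st$durations, st$amplitude),
        file.path(dir, sprintf("events_%s.tsv", st$condition)),
        sep = "\t", col.names = FALSE)
  }
  yaml::write_yaml(list(TR = TR, V = V, n_subjects = length(Y_list),
                        subjects = ids), file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a dataset directory
#'
#' Validates shape consistency: every subject series must have the same `T`
#' and exactly `V` columns; parcel labels must cover every vertex id once.
#'
#' @param dir Dataset directory as written by [write_dataset()].
#' @return List with `coords`, `parcels` (factor), `Y` (named list of
#'   `T x V` matrices), `stims` (list of [stim_train()], possibly empty),
#'   `TR`.
#' @export
read_dataset <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  cdf <- data.table::fread(file.path(dir, "coords.tsv"), data.table = FALSE)
  o <- order(cdf$vertex_id)
  coords <- as.matrix(cdf[o, setdiff(colnames(cdf), "vertex_id"), drop = FALSE])
  assert_finite(coords, "coordinates")
  V <- nrow(coords)
  pdf <- data.table::fread(file.path(dir, "parcels.tsv"), data.table = FALSE)
  if (!setequal(pdf$vertex_id, cdf$vertex_id))
    stopf("parcel labels reference unknown or missing vertex ids")
  parcels <- factor(pdf$parcel_id[order(pdf$vertex_id)])
  subs <- sort(list.files(dir, pattern = "^sub-.*\\.tsv$"))
  Y <- list(); T_vol <- NULL
  for (f in subs) {
    m <- as.matrix(data.table::fread(file.path(dir, f), data.table = FALSE))
    id <- sub("^sub-(.*)\\.tsv$", "\\1", f)
    if (ncol(m) != V)
      stopf("subject %s has %d columns, expected V = %d", id, ncol(m), V)
    if (is.null(T_vol)) T_vol <- nrow(m)
    else if (nrow(m) != T_vol)
      stopf("subject %s has T = %d volumes, expected %d", id, nrow(m), T_vol)
    Y[[id]] <- unname(m)
  }
  evs <- list.files(dir, pattern = "^events_.*\\.tsv$")
  stims <- lapply(evs, function(f)
    read_stimulus_tsv(file.path(dir, f),
                      condition = sub("^events_(.*)\\.tsv$", "\\1", f)))
  list(coords = coords, parcels = parcels, Y = Y, stims = stims,
       TR = meta$TR %||% 1)
}

#' Write inference results
#'
#' Writes the discovery table (TSV), a JSON summary, and a manifest with MD5
#' checksums of the written files.
#'
#' @param inference A `"splash_inference"` object.
#' @param dir Output directory.
#' @return Manifest data frame (file, md5), invisibly.
#' @export
write_results <- function(inference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- as.data.frame(inference)
  tsv <- file.path(dir, "discoveries.tsv")
  data.table::fwrite(tab, tsv, sep = "\t")
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    n_parcels = inference$P, n_subjects = inference$N,
    alpha_parcel = unname(inference$alphas["parcel"]),
    alpha_voxel = unname(inference$alphas["voxel"]),
    selected_parcels = inference$selected,
    q_p = inference$q_p,
    n_discoveries = length(inference$discoveries)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(tsv, js)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}

#' Minimal GIFTI reader (ASCII encoding)
#'
#' Parses GIFTI XML files whose DataArrays use `Encoding="ASCII"`, which
#' covers surface geometry (`NIFTI_INTENT_POINTSET`) and label files. Binary
#' (Base64/GZip) encodings are not supported; convert upstream or use the
#' TSV formats.
#'
#' @param path GIFTI file path.
#' @return List of numeric arrays, one per DataArray, with intent names.
#' @export
read_gifti_ascii <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stopf("the GIFTI adapter needs the xml2 package")
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(arrays)) stopf("no DataArray nodes in %s", path)
  lapply(arrays, function(a) {
    enc <- xml2::xml_attr(a, "Encoding")
    if (!identical(enc, "ASCII"))
      stopf("unsupported GIFTI encoding '%s' (only ASCII)", enc)
    dims <- as.integer(c(xml2::xml_attr(a, "Dim0"), xml2::xml_attr(a, "Dim1")))
    dims <- dims[!is.na(dims)]
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(a, ".//Data")),
                 quiet = TRUE)
    m <- if (length(dims) == 2L)
      matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
    else vals
    attr(m, "intent") <- xml2::xml_attr(a, "Intent")
    m
  })
}

#' NIfTI volume adapter
#'
#' Reads a 4D NIfTI time-series volume and an optional 3D mask into the
#' native `T x V` layout plus voxel coordinates (in voxel units scaled by
#' pixdim).
#'
#' @param path 4D NIfTI file.
#' @param mask Optional 3D NIfTI mask (nonzero = keep); default keeps all
#'   voxels.
#' @return List with `Y` (`T x V`), `coords` (`V x 3`).
#' @export
read_nifti_series <- function(path, mask = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("the NIfTI adapter needs the RNifti package")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stopf("expected a 4D NIfTI volume")
  keep <- if (is.null(mask)) array(TRUE, d[1:3]) else
    as.array(RNifti::readNifti(mask)) != 0
  vox <- which(keep, arr.ind = TRUE)
  pix <- RNifti::pixdim(img)[1:3]
  coords <- sweep(vox, 2L, pix, `*`)
  Ymat <- t(apply(vox, 1L, function(v) img[v[1], v[2], v[3], ]))
  list(Y = t(Ymat), coords = unname(coords))
}
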