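# Volume I/O: NIfTI through RNifti, MetaImage through a minimal reader/writer
# (uncompressed MET_FLOAT / MET_DOUBLE only). The units tag travels in a JSON
# sidecar next to the volume ("<path>.units.json").

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.mha$", lp)) "mha"
  else if (grepl("\\.mhd$", lp)) "mhd"
  else stop("unsupported extension for '", path,
            "'; supported: .nii, .nii.gz, .mha, .mhd")
}

sidecar_path <- function(path) paste0(path, ".units.json")

#' Read / write volumes (NIfTI or MetaImage)
#'
#' `write_volume` stores the array and voxel spacing in the image header and
#' the units tag in a JSON sidecar (`<path>.units.json`); `read_volume`
#' restores all three (units default to `"dimensionless"` when no sidecar is
#' present). Round trips preserve values bit-exactly (doubles) and spacing to
#' better than 1e-6 mm.
#'
#' @param path volume path; `.nii`, `.nii.gz`, `.mha` (local data) or `.mhd`
#'   (header + raw pair).
#' @param img an [image3d] (for writing).
#' @return `read_volume` returns an [image3d]; `write_volume` returns `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    im <- RNifti::readNifti(path)
    vals <- as.array(im)
    if (length(dim(vals)) != 3L) stop("I/O error: expected a 3D volume")
    vals <- array(as.numeric(vals), dim(vals))   # strip niftiImage attributes
    sp <- RNifti::pixdim(im)[1:3]
  } else {
    mi <- read_metaimage(path)
    vals <- mi$values; sp <- mi$spacing
  }
  units <- "dimensionless"
  sc <- sidecar_path(path)
  if (file.exists(sc)) units <- jsonlite::read_json(sc)$units
  image3d(vals, sp, units)
}

#' @rdname read_volume
#' @export
write_volume <- function(img, path) {
  stopifnot(inherits(img, "image3d"))
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    ni <- RNifti::asNifti(img$values)
    RNifti::pixdim(ni) <- img$spacing_mm
    RNifti::writeNifti(ni, path, datatype = "double")
  } else {
    write_metaimage(img, path, local = fmt == "mha")
  }
  jsonlite::write_json(list(units = img$units), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

read_metaimage <- function(path) {
  lines <- character()
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("I/O error: malformed MetaImage header (no data tag)")
    lines <- c(lines, ln)
    if (grepl("^ElementDataFile", ln)) break
  }
  kv <- function(key) {
    hit <- grep(paste0("^", key, "\\s*="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  if (!identical(kv("NDims"), "3")) stop("I/O error: only 3D MetaImage supported")
  if (identical(tolower(kv("CompressedData")), "true"))
    stop("I/O error: compressed MetaImage not supported")
  d <- as.integer(strsplit(kv("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(kv("ElementSpacing"), "\\s+")[[1]])
  typ <- kv("ElementType")
  size <- switch(typ, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("I/O error: unsupported ElementType ", typ))
  datafile <- kv("ElementDataFile")
  n <- prod(d)
  if (identical(datafile, "LOCAL")) {
    raw <- readBin(con, "double", n = n, size = size, endian = "little")
  } else {
    raw <- readBin(file.path(dirname(path), datafile), "double", n = n,
                   size = size, endian = "little")
  }
  if (length(raw) != n) stop("I/O error: truncated MetaImage data")
  list(values = array(raw, d), spacing = sp)
}

write_metaimage <- function(img, path, local = TRUE) {
  d <- dim(img)
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path)),
                                             ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =",
                 paste(format(img$spacing_mm, digits = 17), collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local) {
    writeBin(as.vector(img$values), con, size = 8L, endian = "little")
  } else {
    writeBin(as.vector(img$values),
             file.path(dirname(path), datafile), size = 8L, endian = "little")
  }
  invisible(path)
}
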