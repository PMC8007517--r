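# imzML I/O: XML index (.imzML) + flat binary data (.ibd).
#
# Continuous mode stores one shared m/z axis (float64) followed by one
# float32 intensity block per spectrum. Processed mode stores an m/z block
# and an intensity block per spectrum; on read, per-spectrum centroids are
# binned onto a common axis by a greedy gap rule.

IMS_CONTINUOUS <- "IMS:1000030"
IMS_PROCESSED  <- "IMS:1000031"

ibd_path_for <- function(path) {
  base <- sub("\\.imzml$", "", path, ignore.case = TRUE)
  for (cand in paste0(base, c(".ibd", ".IBD"))) {
    if (file.exists(cand)) return(cand)
  }
  paste0(base, ".ibd")
}

# Deterministic pseudo-UUID from the data payload; avoids touching the
# session RNG so writers are reproducible side-effect-free.
ibd_uuid <- function(intensities) {
  s <- sum(intensities) + length(intensities) * 1e-3
  h <- abs(c(s, s * pi, s * exp(1), sum(intensities^2) + 1,
             nrow(intensities) + 17, ncol(intensities) + 31,
             max(intensities, 0) + 3, min(intensities, 0) + 5))
  as.raw(c(floor(h %% 251), floor((h * 1000) %% 251)))[1:16]
}

#' Write a dataset to an imzML/ibd file pair
#'
#' @param dataset an [msi_dataset()].
#' @param path output `.imzML` path; the `.ibd` is written alongside.
#' @param mode `"continuous"` (shared axis, full intensity vectors) or
#'   `"processed"` (per-spectrum centroid lists; zero-intensity entries are
#'   dropped per spectrum).
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path, mode = c("continuous", "processed")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  mode <- match.arg(mode)
  ibd <- paste0(sub("\\.imzml$", "", path, ignore.case = TRUE), ".ibd")
  n <- nrow(dataset$coords)
  uuid <- ibd_uuid(dataset$intensities)

  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16

  # per-spectrum bookkeeping: offsets/lengths for mz and intensity blocks
  spec <- vector("list", n)
  if (mode == "continuous") {
    mz_off <- offset
    mz_len <- length(dataset$mz_axis)
    writeBin(as.numeric(dataset$mz_axis), con, size = 8, endian = "little")
    offset <- offset + 8 * mz_len
    for (i in seq_len(n)) {
      v <- as.numeric(dataset$intensities[i, ])
      writeBin(v, con, size = 4, endian = "little")
      spec[[i]] <- list(mz_off = mz_off, mz_len = mz_len,
                        int_off = offset, int_len = length(v))
      offset <- offset + 4 * length(v)
    }
  } else {
    for (i in seq_len(n)) {
      keep <- which(dataset$intensities[i, ] > 0)
      if (length(keep) == 0L) keep <- 1L  # keep files parseable
      mzv <- as.numeric(dataset$mz_axis[keep])
      iv <- as.numeric(dataset$intensities[i, keep])
      mz_off <- offset
      writeBin(mzv, con, size = 8, endian = "little")
      offset <- offset + 8 * length(mzv)
      writeBin(iv, con, size = 4, endian = "little")
      spec[[i]] <- list(mz_off = mz_off, mz_len = length(mzv),
                        int_off = offset, int_len = length(iv))
      offset <- offset + 4 * length(iv)
    }
  }

  mode_acc <- if (mode == "continuous") IMS_CONTINUOUS else IMS_PROCESSED
  uuid_str <- paste0("{", paste(sprintf("%02x", as.integer(uuid)),
                                collapse = ""), "}")
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="PSI-MS" URI="http://psidev.info/ms"/>',
    '<cv id="IMS" fullName="IMS" URI="http://www.maldi-msi.org/imzml"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    sprintf('<cvParam cvRef="IMS" accession="%s" name="%s"/>',
            mode_acc, mode),
    sprintf(paste0('<cvParam cvRef="IMS" accession="IMS:1000080" ',
                   'name="universally unique identifier" value="%s"/>'),
            uuid_str),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scansettings1">',
    sprintf(paste0('<cvParam cvRef="IMS" accession="IMS:1000046" ',
                   'name="pixel size x" value="%s"/>'),
            esc(format(dataset$pixel_size_um, digits = 12))),
    '</scanSettings></scanSettingsList>',
    sprintf('<run id="run1"><spectrumList count="%d">', n)
  )

  spectra_xml <- vapply(seq_len(n), function(i) {
    s <- spec[[i]]
    paste0(
      sprintf('<spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">',
              i, i - 1L, s$int_len),
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
              dataset$coords[i, 1] + 1L),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
              dataset$coords[i, 2] + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', s$mz_len),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>', s$mz_off),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>', 8 * s$mz_len),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', s$int_len),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>', s$int_off),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>', 4 * s$int_len),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  writeLines(c(out, spectra_xml, '</spectrumList></run></mzML>'), path)
  invisible(path)
}

#' Read an imzML/ibd file pair
#'
#' Continuous-mode data keeps its shared acquisition axis. Processed-mode
#' centroids from all spectra are pooled, sorted, and merged greedily from
#' the left: a gap larger than `bin_tol` between consecutive sorted m/z
#' values starts a new bin, and each bin's center is the mean of its member
#' m/z values. Per pixel, intensities falling in one bin are summed.
#'
#' @param path `.imzML` file; the `.ibd` must sit alongside.
#' @param bin_tol greedy binning gap tolerance in Da (processed mode only).
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path, bin_tol = 0.01) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0) stopf("imzML format error: empty file")
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) stopf("missing ibd file for %s", path)

  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("imzML format error: %s",
                                            conditionMessage(e)))
  xml2::xml_ns_strip(doc)

  acc <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//fileContent/cvParam"), "accession")
  mode <- if (IMS_PROCESSED %in% acc) "processed" else "continuous"

  ps_node <- xml2::xml_find_first(
    doc, ".//scanSettings/cvParam[@accession='IMS:1000046']")
  pixel_size <- if (inherits(ps_node, "xml_missing")) 1 else
    as.numeric(xml2::xml_attr(ps_node, "value"))

  # byte width per referenceable param group
  grp_size <- vapply(
    xml2::xml_find_all(doc, ".//referenceableParamGroup"),
    function(g) {
      a <- xml2::xml_attr(xml2::xml_find_all(g, "./cvParam"), "accession")
      if ("MS:1000523" %in% a) 8L else if ("MS:1000521" %in% a) 4L else 8L
    }, integer(1))
  names(grp_size) <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//referenceableParamGroup"), "id")

  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (length(spectra) == 0L) stopf("imzML format error: no spectra")

  parse_spectrum <- function(sp) {
    scan_cv <- xml2::xml_find_all(sp, ".//scan/cvParam")
    sa <- xml2::xml_attr(scan_cv, "accession")
    sv <- as.numeric(xml2::xml_attr(scan_cv, "value"))
    x <- sv[match("IMS:1000050", sa)] - 1
    y <- sv[match("IMS:1000051", sa)] - 1
    arrs <- lapply(xml2::xml_find_all(sp, ".//binaryDataArray"), function(b) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(b, "./referenceableParamGroupRef"), "ref")
      cv <- xml2::xml_find_all(b, "./cvParam")
      a <- xml2::xml_attr(cv, "accession")
      v <- xml2::xml_attr(cv, "value")
      list(ref = ref,
           len = as.numeric(v[match("IMS:1000103", a)]),
           off = as.numeric(v[match("IMS:1000102", a)]))
    })
    names(arrs) <- vapply(arrs, `[[`, character(1), "ref")
    list(x = x, y = y, arrs = arrs)
  }
  info <- lapply(spectra, parse_spectrum)

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  read_block <- function(off, len, size) {
    seek(con, where = off, origin = "start")
    readBin(con, "numeric", n = len, size = size, endian = "little")
  }

  coords <- cbind(x = vapply(info, `[[`, numeric(1), "x"),
                  y = vapply(info, `[[`, numeric(1), "y"))

  if (mode == "continuous") {
    lens <- vapply(info, function(s) s$arrs$mzArray$len, numeric(1))
    if (length(unique(lens)) != 1L ||
        length(unique(vapply(info, function(s) s$arrs$intensityArray$len,
                             numeric(1)))) != 1L) {
      stopf("imzML format error: inconsistent spectrum lengths in continuous mode")
    }
    mz_axis <- read_block(info[[1]]$arrs$mzArray$off, lens[1],
                          grp_size[["mzArray"]])
    intens <- t(vapply(info, function(s) {
      read_block(s$arrs$intensityArray$off, s$arrs$intensityArray$len,
                 grp_size[["intensityArray"]])
    }, numeric(lens[1])))
    return(msi_dataset(coords, mz_axis, intens, pixel_size_um = pixel_size,
                       meta = list(source = path, mode = mode)))
  }

  # processed: pool all centroids, greedy-bin, sum per pixel per bin
  peaks <- lapply(seq_along(info), function(i) {
    s <- info[[i]]
    mzv <- read_block(s$arrs$mzArray$off, s$arrs$mzArray$len,
                      grp_size[["mzArray"]])
    iv <- read_block(s$arrs$intensityArray$off, s$arrs$intensityArray$len,
                     grp_size[["intensityArray"]])
    if (length(mzv) != length(iv)) {
      stopf("imzML format error: mz/intensity length mismatch in spectrum %d", i)
    }
    data.frame(pixel = i, mz = mzv, intensity = iv)
  })
  pk <- do.call(rbind, peaks)
  bins <- greedy_bin(pk$mz, bin_tol)
  mz_axis <- bins$centers
  intens <- matrix(0, length(info), length(mz_axis))
  idx <- cbind(pk$pixel, bins$assignment)
  for (r in seq_len(nrow(pk))) {
    intens[idx[r, 1], idx[r, 2]] <- intens[idx[r, 1], idx[r, 2]] +
      pk$intensity[r]
  }
  msi_dataset(coords, mz_axis, intens, pixel_size_um = pixel_size,
              meta = list(source = path, mode = mode,
                          bin_tol = as.character(bin_tol)))
}

#' Greedy left-to-right m/z binning
#'
#' Sorts the values; a gap greater than `tol` between consecutive sorted
#' values starts a new bin. Bin center is the mean of members.
#'
#' @param mz numeric vector of centroid m/z values.
#' @param tol gap tolerance in Da.
#' @return list with `centers` (sorted bin centers) and `assignment`
#'   (bin index per input value, in input order).
#' @export
greedy_bin <- function(mz, tol) {
  if (length(mz) == 0L) stopf("no m/z values to bin")
  o <- order(mz)
  s <- mz[o]
  bin_sorted <- cumsum(c(1L, as.integer(diff(s) > tol)))
  centers <- as.numeric(tapply(s, bin_sorted, mean))
  assignment <- integer(length(mz))
  assignment[o] <- bin_sorted
  list(centers = centers, assignment = assignment)
}
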