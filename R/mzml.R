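# Minimal mzML I/O: uncompressed 64-bit float arrays, MS1 profile spectra.
# Covers exactly what the synthetic generator writes and the preprocessing
# readers need; it is not a general-purpose mzML implementation.

.encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8,
                                endian = "little"))
}

.decode_doubles <- function(b64) {
  readBin(jsonlite::base64_dec(b64), "numeric", n = 1e8, size = 8,
          endian = "little")
}

#' Write a recording as mzML
#'
#' Emits a minimal mzML 1.1 document: one MS1 spectrum per scan with
#' uncompressed little-endian 64-bit m/z and intensity arrays and the scan
#' start time in seconds.
#'
#' @param scan_series A `scan_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(scan_series, path) {
  n <- length(scan_series$scans)
  pol_acc <- if (identical(scan_series$polarity, "neg"))
    c("MS:1000129", "negative scan") else c("MS:1000130", "positive scan")
  doc <- xml2::xml_new_root("mzML",
    xmlns = "http://psi.hupo.org/ms/mzml", version = "1.1.0")
  run <- xml2::xml_add_child(doc, "run", id = scan_series$sample_id)
  sl <- xml2::xml_add_child(run, "spectrumList", count = as.character(n))
  for (i in seq_len(n)) {
    sc <- scan_series$scans[[i]]
    sp <- xml2::xml_add_child(sl, "spectrum",
      index = as.character(i - 1L),
      id = sprintf("scan=%d", i),
      defaultArrayLength = as.character(length(sc$mz)))
    xml2::xml_add_child(sp, "cvParam", cvRef = "MS", accession = "MS:1000511",
                        name = "ms level", value = "1")
    xml2::xml_add_child(sp, "cvParam", cvRef = "MS", accession = "MS:1000128",
                        name = "profile spectrum", value = "")
    xml2::xml_add_child(sp, "cvParam", cvRef = "MS", accession = pol_acc[1],
                        name = pol_acc[2], value = "")
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    scn <- xml2::xml_add_child(scl, "scan")
    xml2::xml_add_child(scn, "cvParam", cvRef = "MS", accession = "MS:1000016",
                        name = "scan start time", value = as.character(sc$time),
                        unitName = "second")
    bl <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    for (arr in list(c("MS:1000514", "m/z array"),
                     c("MS:1000515", "intensity array"))) {
      vals <- if (arr[1] == "MS:1000514") sc$mz else sc$intensity
      ba <- xml2::xml_add_child(bl, "binaryDataArray")
      xml2::xml_add_child(ba, "cvParam", cvRef = "MS",
                          accession = "MS:1000523", name = "64-bit float",
                          value = "")
      xml2::xml_add_child(ba, "cvParam", cvRef = "MS",
                          accession = "MS:1000576", name = "no compression",
                          value = "")
      xml2::xml_add_child(ba, "cvParam", cvRef = "MS", accession = arr[1],
                          name = arr[2], value = "")
      xml2::xml_add_child(ba, "binary", .encode_doubles(vals))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an mzML file into a `scan_series`
#'
#' Supports the subset written by [write_mzml()]: MS1 spectra with
#' uncompressed 64-bit float arrays (profile or centroid).
#'
#' @param path mzML file.
#' @param sample_id Optional sample id; defaults to the run id.
#' @return A `scan_series`.
#' @export
read_mzml <- function(path, sample_id = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  run <- xml2::xml_find_first(doc, ".//run")
  if (is.null(sample_id))
    sample_id <- xml2::xml_attr(run, "id")
  pol <- "pos"
  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  scans <- lapply(spectra, function(sp) {
    if (length(xml2::xml_find_first(sp, ".//cvParam[@accession='MS:1000129']")) &&
        !inherits(xml2::xml_find_first(sp, ".//cvParam[@accession='MS:1000129']"),
                  "xml_missing"))
      pol <<- "neg"
    t <- as.numeric(xml2::xml_attr(
      xml2::xml_find_first(sp, ".//cvParam[@accession='MS:1000016']"), "value"))
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- NULL; inten <- NULL
    for (ba in arrays) {
      b64 <- xml2::xml_text(xml2::xml_find_first(ba, ".//binary"))
      vals <- .decode_doubles(b64)
      if (!inherits(xml2::xml_find_first(ba, ".//cvParam[@accession='MS:1000514']"),
                    "xml_missing")) mz <- vals else inten <- vals
    }
    list(time = t, mz = mz, intensity = inten)
  })
  scans <- scans[order(vapply(scans, `[[`, 0, "time"))]
  structure(list(scans = scans, polarity = pol, sample_id = sample_id),
            class = "scan_series")
}
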