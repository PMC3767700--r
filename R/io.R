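# TIFF persistence helpers.
#
# tiff::writeTIFF stores samples in [0, 1]; physical maps (mu in 1/m, delta
# ~1e-7, raw counts) are therefore min/max-rescaled per page and the ranges
# kept in a JSON sidecar so that .read_float_tiff restores exact values
# (up to float32 quantization of the stored samples).

.write_float_tiff <- function(pages, path, sidecar = paste0(path, ".json"),
                              extra = list()) {
  if (is.matrix(pages)) pages <- list(pages)
  ranges <- lapply(pages, function(p) {
    c(min = min(p), max = max(p))
  })
  scaled <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    r <- ranges[[i]]
    if (r["max"] > r["min"]) (p - r["min"]) / (r["max"] - r["min"])
    else p * 0
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(list(pages = length(pages),
                 ranges = lapply(ranges, unname),
                 dim = dim(pages[[1]])),
            extra)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_float_tiff <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  get_range <- function(i) {
    r <- meta$ranges
    if (is.matrix(r)) r[i, ] else unlist(r[[i]])
  }
  lapply(seq_along(pages), function(i) {
    r <- get_range(i)
    m <- pages[[i]] * (r[2] - r[1]) + r[1]
    matrix(m, nrow = meta$dim[1], ncol = meta$dim[2])
  })
}

# JSON provenance sidecar: md5 of the payload file plus free-form fields
.write_provenance <- function(path, stage, inputs = list(), params = list()) {
  side <- paste0(path, ".provenance.json")
  md5 <- unname(tools::md5sum(path))
  jsonlite::write_json(list(stage = stage, file = basename(path), md5 = md5,
                            inputs = inputs, params = params,
                            written = format(Sys.time(), tz = "UTC")),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}
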