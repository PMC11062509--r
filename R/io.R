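# Real-data entry points: CSV weather and phenotypes, GeoJSON plot maps,
# TIFF band rasters, VCF genotypes (+ label sheet).

#' Read and write weather CSV (`date,tmean`)
#'
#' @param weather An `sg_weather` (or `date`/`tmean` data frame).
#' @param path File path.
#' @return `read_weather_csv()` returns an `sg_weather`.
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(data.frame(date = format(as.Date(weather$date)),
                              tmean = weather$tmean),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sg_assert(all(c("date", "tmean") %in% names(df)),
            "weather CSV needs columns date,tmean")
  df$date <- as.Date(df$date)
  sg_assert(all(diff(as.numeric(df$date)) == 1),
            "weather dates must be strictly increasing daily with no gaps")
  sg_assert(all(is.finite(df$tmean)), "tmean must be finite")
  structure(df[, c("date", "tmean")], class = c("sg_weather", "data.frame"))
}

#' Read and write GeoJSON plot maps
#'
#' Plots are rectangles in raster pixel coordinates (x = column, y = row,
#' 0-based, half-open); each feature carries its `plot_id` property. The
#' raster dimensions and panel region travel in the top-level `properties`.
#'
#' @param plots An `sg_plotmap`.
#' @param path File path.
#' @return `read_plot_map_geojson()` returns an `sg_plotmap`.
#' @export
write_plot_map_geojson <- function(plots, path) {
  sg_assert(inherits(plots, "sg_plotmap"), "plots must be an sg_plotmap")
  feat <- lapply(seq_len(nrow(plots$plots)), function(i) {
    p <- plots$plots[i, ]
    ring <- list(c(p$c0, p$r0), c(p$c1, p$r0), c(p$c1, p$r1),
                 c(p$c0, p$r1), c(p$c0, p$r0))
    list(type = "Feature",
         properties = list(plot_id = p$plot_id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(dims = plots$dims,
                               panel_region = plots$panel_region),
             features = feat)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plot_map_geojson
#' @export
read_plot_map_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  sg_assert(identical(gj$type, "FeatureCollection"),
            "not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(pt) as.numeric(pt[[1]]), 0)
    ys <- vapply(ring, function(pt) as.numeric(pt[[2]]), 0)
    data.frame(plot_id = f$properties$plot_id,
               r0 = min(ys), c0 = min(xs), r1 = max(ys), c1 = max(xs),
               stringsAsFactors = FALSE)
  })
  plots <- do.call(rbind, rows)
  dims <- unlist(gj$properties$dims)
  panel <- unlist(gj$properties$panel_region)
  plot_map(plots, dims, if (length(panel)) panel else NULL)
}

#' Write and read a band stack as per-band TIFF files
#'
#' One 32-bit float TIFF per band, named `<prefix>_<band>.tif`; the flight
#' date and panel region are stored in a `<prefix>_meta.json` sidecar.
#' Values are stored as-is (digital numbers or reflectance).
#'
#' @param stack An `sg_bandstack`.
#' @param prefix Path prefix (directory must exist).
#' @return `read_band_tiff()` returns an `sg_bandstack`.
#' @export
write_band_tiff <- function(stack, prefix) {
  sg_assert(inherits(stack, "sg_bandstack"), "stack must be an sg_bandstack")
  # TIFF samples live in [0, 1]; digital numbers are rescaled by a per-band
  # factor recorded in the sidecar and undone on read
  scale <- vapply(sg_bands(), function(b) {
    mx <- max(stack$bands[[b]], 0, na.rm = TRUE)
    if (mx > 1) mx else 1
  }, 0)
  for (b in sg_bands()) {
    tiff::writeTIFF(stack$bands[[b]] / scale[[b]],
                    paste0(prefix, "_", b, ".tif"), bits.per.sample = 32L)
  }
  jsonlite::write_json(list(date = format(stack$date),
                            panel_region = stack$panel_region,
                            scale = as.list(scale)),
                       paste0(prefix, "_meta.json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' @rdname write_band_tiff
#' @export
read_band_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  scale <- meta$scale
  bands <- lapply(sg_bands(), function(b) {
    m <- tiff::readTIFF(paste0(prefix, "_", b, ".tif"))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m * (if (!is.null(scale[[b]])) scale[[b]] else 1)
  })
  names(bands) <- sg_bands()
  band_stack(bands, as.Date(meta$date),
             if (length(meta$panel_region)) unlist(meta$panel_region)
             else NULL)
}

#' Write a genotype panel as VCF (plus label CSV)
#'
#' Diploid unphased genotypes (`0/0`, `0/1`, `1/1`); the accession label
#' sheet is written alongside as `<path>.labels.csv`. The VCF is
#' bgzip/gzip-compressed (`.vcf.gz`), the format `vcfR` emits.
#'
#' @param geno An `sg_geno`.
#' @param path Output path (a `.gz` suffix is appended by `vcfR` if
#'   missing).
#' @return Invisibly, the path written.
#' @export
write_genotypes_vcf <- function(geno, path) {
  sg_assert(inherits(geno, "sg_geno"), "geno must be an sg_geno")
  n_snp <- nrow(geno$map)
  fix <- cbind(CHROM = geno$map$chrom, POS = as.character(geno$map$pos),
               ID = geno$map$snp, REF = geno$map$ref, ALT = geno$map$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- t(geno$dosage)
  gt <- matrix(NA_character_, n_snp, nrow(geno$dosage))
  ok <- !is.na(dos)
  gt[ok] <- gt_codes[as.character(dos[ok])]
  gt[!ok] <- "./."
  gt <- cbind(FORMAT = "GT", gt)
  colnames(gt) <- c("FORMAT", rownames(geno$dosage))
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = c("##fileformat=VCFv4.2",
                             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                    fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  utils::write.csv(geno$labels, paste0(path, ".labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype panel from VCF (plus optional label CSV)
#'
#' @param path VCF path (`.vcf` or `.vcf.gz`).
#' @param labels_path Label CSV (`accession` + label columns); defaults to
#'   `<path>.labels.csv` when present.
#' @return An `sg_geno`.
#' @export
read_genotypes_vcf <- function(path, labels_path = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("\\|", "/", gt)
  dosage <- matrix(NA_integer_, ncol(gt), nrow(gt))
  dosage_map <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L)
  dos <- dosage_map[alleles]
  dosage <- t(matrix(dos, nrow(gt), ncol(gt)))
  fix <- vcfR::getFIX(v)
  snp <- fix[, "ID"]
  no_id <- is.na(snp) | snp == "."
  snp[no_id] <- sprintf("s%s%s", fix[no_id, "CHROM"], fix[no_id, "POS"])
  dimnames(dosage) <- list(colnames(gt), snp)
  if (is.null(labels_path) && file.exists(paste0(path, ".labels.csv"))) {
    labels_path <- paste0(path, ".labels.csv")
  }
  labels <- if (!is.null(labels_path)) {
    utils::read.csv(labels_path, stringsAsFactors = FALSE)
  } else {
    data.frame(accession = colnames(gt), flowering = NA, era = NA,
               region = NA, group = NA, subpop = NA,
               stringsAsFactors = FALSE)
  }
  labels <- labels[match(colnames(gt), labels$accession), , drop = FALSE]
  structure(list(dosage = dosage,
                 map = data.frame(snp = snp, chrom = fix[, "CHROM"],
                                  pos = as.numeric(fix[, "POS"]),
                                  ref = fix[, "REF"], alt = fix[, "ALT"],
                                  stringsAsFactors = FALSE),
                 labels = labels),
            class = "sg_geno")
}

#' Write and read the RSGS phenotype CSV
#'
#' Long format `accession,index,stage,rss,rsgs,rsgs_corrected,k` — the GWAS
#' phenotype file.
#'
#' @param tbl An `sg_rsgs` table.
#' @param path File path.
#' @return `read_rsgs_csv()` returns an `sg_rsgs`.
#' @export
write_rsgs_csv <- function(tbl, path) {
  sg_assert(inherits(tbl, "sg_rsgs"), "tbl must be an sg_rsgs")
  out <- data.frame(accession = tbl$accession, index = tbl$index,
                    stage = tbl$stage, rss = tbl$rss, rsgs = tbl$rsgs,
                    rsgs_corrected = tbl$sg, k = tbl$k)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rsgs_csv
#' @export
read_rsgs_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "index", "stage", "rss", "rsgs", "rsgs_corrected",
            "k")
  sg_assert(all(need %in% names(df)), "not an RSGS phenotype CSV")
  df$sg <- df$rsgs_corrected
  df$trait <- sprintf("SG_%s%s", toupper(df$index),
                      sub("^S", "", df$stage))
  class(df) <- c("sg_rsgs", "data.frame")
  df
}
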