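#' Read and write the package's delimited formats
#'
#' Genotypes are written as a CSV with progeny rows and marker columns
#' (tokens AC/AD/BC/BD, NA when missing), maps as 4-column tables
#' (marker, chrom, cM, bp), phenotypes long, and weather per-station with
#' ISO-8601 dates. All files are UTF-8, comma-delimited, '.' decimal.
#'
#' @param g A `fourway_geno`.
#' @param path Output file (genotypes) or file prefix (`write_genotypes`
#'   writes `<path>_geno.csv` and `<path>_map.csv`).
#' @return `write_*` return the path(s) invisibly; `read_genotypes` returns
#'   a `fourway_geno`.
#' @name qtlscape-io
NULL

#' @rdname qtlscape-io
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "fourway_geno"))
  gpath <- paste0(path, "_geno.csv")
  mpath <- paste0(path, "_map.csv")
  tokens <- tibble::as_tibble(geno_calls(g), rownames = "progeny")
  readr::write_csv(tokens, gpath, na = "NA")
  readr::write_csv(g$map, mpath)
  invisible(c(gpath, mpath))
}

#' @rdname qtlscape-io
#' @export
read_genotypes <- function(path) {
  tokens <- readr::read_csv(paste0(path, "_geno.csv"), na = "NA",
                            show_col_types = FALSE)
  map <- readr::read_csv(paste0(path, "_map.csv"), show_col_types = FALSE)
  mat <- as.matrix(tokens[, -1])
  geno <- matrix(match(mat, geno_levels()), nrow(mat),
                 dimnames = list(tokens$progeny, colnames(mat)))
  structure(list(geno = geno, map = tibble::as_tibble(map)),
            class = "fourway_geno")
}
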