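#' Construct, read and query an LD source
#'
#' An [LDSource-class] stores precomputed pairwise r-squared values
#' between variants (tab-separated triples on disk) plus its declared
#' completeness domain. Pairs not listed but with both members in the
#' domain are taken to have r-squared 0.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `r2`.
#' @param domain character vector of covered variant ids; defaults to
#'   the ids appearing in `pairs`.
#' @return an [LDSource-class] object.
#' @examples
#' ld <- ldSource(data.frame(id_a = "v1", id_b = "v2", r2 = 0.9),
#'                domain = c("v1", "v2", "v3"))
#' ldR2(ld, "v1", "v2")   # 0.9
#' ldR2(ld, "v1", "v3")   # 0 (covered, unlisted)
#' ldR2(ld, "v1", "v9")   # NA (outside the domain)
#' @export
ldSource <- function(pairs = data.frame(id_a = character(),
                                        id_b = character(), r2 = numeric()),
                     domain = NULL) {
  pairs$id_a <- as.character(pairs$id_a)
  pairs$id_b <- as.character(pairs$id_b)
  pairs$r2 <- as.numeric(pairs$r2)
  if (is.null(domain)) domain <- unique(c(pairs$id_a, pairs$id_b))
  new("LDSource", pairs = pairs, domain = as.character(domain))
}

#' @describeIn ldSource pairwise r-squared between variants `a` and `b`
#'   (vectorized): 1 on the diagonal, 0 for unlisted covered pairs, `NA`
#'   when either variant lies outside the domain.
#' @param ld an [LDSource-class] object.
#' @param a,b variant ids.
#' @export
setMethod("ldR2", "LDSource", function(ld, a, b) {
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  lut <- stats::setNames(ld@pairs$r2, key(ld@pairs$id_a, ld@pairs$id_b))
  out <- unname(lut[key(a, b)])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out[!(a %in% ld@domain) | !(b %in% ld@domain)] <- NA_real_
  out[a == b] <- 1
  out
})

#' @describeIn ldSource the declared completeness domain.
#' @export
setMethod("ldDomain", "LDSource", function(ld) ld@domain)

setMethod("show", "LDSource", function(object) {
  cat("LDSource: ", nrow(object@pairs), " stored pair(s), domain of ",
      length(object@domain), " variant(s)\n", sep = "")
})

#' @describeIn ldSource read an LD table (tab-separated `id_a`, `id_b`,
#'   `r2`; optional comment header line `#domain: id1,id2,...` declares
#'   the completeness domain explicitly).
#' @param path file path.
#' @export
readLDSource <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  domain <- NULL
  if (startsWith(first, "#domain:")) {
    domain <- strsplit(sub("^#domain:\\s*", "", first), ",")[[1]]
    domain <- trimws(domain)
    domain <- domain[nzchar(domain)]
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#",
                           colClasses = c("character", "character",
                                          "numeric"))
  names(tab) <- c("id_a", "id_b", "r2")
  ldSource(tab, domain = domain)
}

#' @describeIn ldSource write the LD table with its domain header.
#' @export
writeLDSource <- function(ld, path) {
  stopifnot(is(ld, "LDSource"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#domain: ", paste(ld@domain, collapse = ",")), con)
  utils::write.table(ld@pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
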