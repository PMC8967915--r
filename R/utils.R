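#' @importFrom methods is as new
#' @importFrom stats median mad quantile p.adjust prcomp kmeans rnorm runif
#'   rlnorm rbeta rgamma rbinom rmultinom dist var sd predict smooth.spline
#'   setNames
#' @importFrom utils read.delim write.table packageVersion head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib scqckit, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-operation seed from a pipeline-level seed
#'
#' A single pipeline seed fans out to one seed per operation by hashing the
#' operation name, so adding or removing one operation does not perturb the
#' random streams of the others.
#'
#' @param seed integer pipeline-level seed.
#' @param op character scalar, operation name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(op))
  h <- digest::digest(op, algo = "crc32", serialize = FALSE)
  offs <- strtoi(substr(h, 1L, 7L), base = 16L)
  as.integer((as.numeric(seed) + offs) %% (.Machine$integer.max - 1))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# gzip a file in place (path -> path.gz), returning the new path.
gzipFile <- function(path) {
  out <- paste0(path, ".gz")
  con_in <- file(path, "rb")
  con_out <- gzfile(out, "wb")
  while (length(chunk <- readBin(con_in, "raw", 1024L * 512L)) > 0L)
    writeBin(chunk, con_out)
  close(con_in); close(con_out)
  unlink(path)
  out
}

# Open a text connection transparently handling .gz suffixes.
openText <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

readLinesGz <- function(path) {
  con <- openText(path)
  on.exit(close(con))
  readLines(con)
}

readTSVGz <- function(path, ...) {
  con <- openText(path)
  on.exit(try(close(con), silent = TRUE))
  read.delim(con, ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
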