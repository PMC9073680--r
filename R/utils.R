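`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic 31-bit string hash (djb2 variant) used to derive named
# substreams from one user seed. Adding a new named component never
# shifts the draws of an existing one.
.string_hash <- function(x) {
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

#' Derive a named random-number substream seed
#'
#' Fans a single user-facing seed out into per-component seeds so that
#' each stage of the simulator draws from its own stream.
#'
#' @param seed integer master seed.
#' @param component character stream name.
#' @return integer seed in `[0, 2^31)`.
#' @export
stream_seed <- function(seed, component) {
  s <- (as.numeric(seed) %% 65536) * 32749 + .string_hash(component)
  as.integer(s %% 2147483647)
}

.set_stream <- function(seed, component) {
  set.seed(stream_seed(seed, component))
}

#' Length of an inversion from printed breakpoints
#'
#' Interval arithmetic on 1-based inclusive breakpoint coordinates as
#' reported by read-pair structural-variant callers: the span is
#' `end - start` (e.g. breakpoints 5,414,046 and 13,233,866 give
#' 7,819,820 bp, i.e. 7.82 Mb).
#'
#' @param start,end 1-based breakpoint positions, `end > start`.
#' @return span in bp.
#' @export
breakpoint_span <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end), end > start)
  end - start
}

#' Inversion carrier frequency from genotype class counts
#'
#' Tallies carrier chromosomes from per-sample inversion genotypes.
#' Diploid samples contribute two chromosomes (homozygous inverted = 2
#' carriers, heterozygous = 1); hemizygous samples (female Z) contribute
#' one.
#'
#' @param hom_inverted,het,hom_ancestral diploid genotype class counts.
#' @param hemi_carrier,hemi_non_carrier hemizygous sample counts.
#' @return list with `carriers`, `total` chromosomes and `frequency`.
#' @examples
#' carrier_frequency(hom_inverted = 4, het = 3, hom_ancestral = 1)$frequency # 0.6875
#' @export
carrier_frequency <- function(hom_inverted = 0, het = 0, hom_ancestral = 0,
                              hemi_carrier = 0, hemi_non_carrier = 0) {
  carriers <- 2 * hom_inverted + het + hemi_carrier
  total <- 2 * (hom_inverted + het + hom_ancestral) + hemi_carrier + hemi_non_carrier
  if (total == 0) stop("no samples tallied")
  list(carriers = carriers, total = total, frequency = carriers / total)
}

# "11/16 (0.6875)" style rendering used in reports
format_fraction <- function(carriers, total, digits = 4) {
  sprintf("%d/%d (%s)", carriers, total,
          format(round(carriers / total, digits), nsmall = 0))
}

# md5 digest of an arbitrary R object via base tools; used for stage
# caching in the pipeline.
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
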