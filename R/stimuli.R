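#' Proportion of segments deleted at a fragmentation level
#'
#' Fragmented versions of a line drawing are produced by cumulative random
#' deletion of its segments. Level 1 is the complete picture and level 7 the
#' most fragmented; the deleted proportion at level L is `1 - 0.7^(L - 1)`.
#'
#' @param level Integer fragmentation level(s) in 1..7.
#' @return Numeric fraction(s) in \[0, 1\].
#' @examples
#' deletion_proportion(1)  # 0
#' deletion_proportion(4)  # 0.657
#' @export
deletion_proportion <- function(level) {
  if (!is.numeric(level) || any(is.na(level)) ||
      any(level != round(level)) || any(level < 1) || any(level > 7)) {
    stop("'level' must be an integer (or vector of integers) in 1..7")
  }
  1 - 0.7^(level - 1)
}

#' Construct a picture object
#'
#' A picture is an ordered set of drawable segment identifiers. Any toy
#' segment list suffices; the analysis code never needs actual artwork.
#'
#' @param picture_id Character scalar identifier.
#' @param n_segments Number of segments (>= 1); segment ids are `1:n_segments`.
#' @return An object of class `picture`.
#' @export
picture <- function(picture_id, n_segments) {
  if (!is.character(picture_id) || length(picture_id) != 1L || !nzchar(picture_id)) {
    stop("'picture_id' must be a non-empty string")
  }
  n_segments <- as.integer(n_segments)
  if (is.na(n_segments) || n_segments < 1L) stop("'n_segments' must be >= 1")
  structure(
    list(picture_id = picture_id, segments = seq_len(n_segments),
         n_segments = n_segments),
    class = "picture"
  )
}

# round half away from zero; base round() is banker's rounding
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Generate the seven nested fragmentation levels of a picture
#'
#' Segments are deleted randomly and cumulatively so the retained sets are
#' nested: level 1 keeps every segment and each later level deletes further
#' segments following a single seeded deletion order. The number deleted at
#' level L is `round(n_segments * deletion_proportion(L))` (half away from
#' zero).
#'
#' @param pic A [picture()].
#' @param seed Integer seed; the same seed reproduces the sequence exactly.
#' @return An object of class `fragment_sequence` with elements `picture_id`,
#'   `levels` (list of retained segment-id vectors, levels 1..7),
#'   `deletion_order` and `seed`.
#' @export
fragment_picture <- function(pic, seed) {
  if (!inherits(pic, "picture")) stop("'pic' must be a picture object")
  if (pic$n_segments < 1L) stop("picture has no segments")
  n <- pic$n_segments
  rng <- local_rng(seed)
  deletion_order <- rng$sample(pic$segments, n)
  levels <- lapply(1:7, function(L) {
    n_del <- as.integer(round_half_up(n * deletion_proportion(L)))
    if (n_del == 0L) pic$segments else sort(setdiff(pic$segments, deletion_order[seq_len(n_del)]))
  })
  names(levels) <- paste0("level", 1:7)
  structure(
    list(picture_id = pic$picture_id, levels = levels,
         deletion_order = deletion_order, seed = as.integer(seed)),
    class = "fragment_sequence"
  )
}

#' Scramble an image by permuting a 16 x 16 grid of tiles
#'
#' Control stimuli are made by dividing an image into a 16-by-16 tiling
#' (256 tiles) and permuting the tiles. Images whose dimensions are not
#' divisible by 16 are zero-padded symmetrically first. The multiset of tile
#' contents — and hence the global pixel histogram — is preserved.
#'
#' @param image 2-D numeric matrix of pixel intensities.
#' @param seed Integer seed for the tile permutation.
#' @return Scrambled matrix (padded dimensions if padding was required), with
#'   the permutation stored in attribute `"tile_permutation"`.
#' @export
scramble_picture <- function(image, seed) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("'image' must be a 2-D numeric matrix")
  }
  pad_to <- function(d) as.integer(ceiling(d / 16) * 16)
  nr <- pad_to(nrow(image)); nc <- pad_to(ncol(image))
  if (nr != nrow(image) || nc != ncol(image)) {
    padded <- matrix(0, nr, nc)
    r0 <- (nr - nrow(image)) %/% 2L
    c0 <- (nc - ncol(image)) %/% 2L
    padded[r0 + seq_len(nrow(image)), c0 + seq_len(ncol(image))] <- image
    image <- padded
  }
  th <- nr %/% 16L; tw <- nc %/% 16L
  rng <- local_rng(seed)
  perm <- rng$sample(256L, 256L)
  out <- matrix(0, nr, nc)
  for (k in seq_len(256L)) {
    src <- perm[k]
    si <- (src - 1L) %/% 16L; sj <- (src - 1L) %% 16L
    di <- (k - 1L) %/% 16L;  dj <- (k - 1L) %% 16L
    out[di * th + seq_len(th), dj * tw + seq_len(tw)] <-
      image[si * th + seq_len(th), sj * tw + seq_len(tw)]
  }
  attr(out, "tile_permutation") <- perm
  out
}
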