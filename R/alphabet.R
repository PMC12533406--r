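#' Residue alphabet for collagen-mimetic peptides
#'
#' The 20 canonical one-letter amino-acid codes plus `"O"` for
#' (4R)-4-hydroxyproline (Hyp), the dominant Yaa residue in collagen.
#'
#' @format Character vector of length 21.
#' @export
CMP_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "O", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname CMP_ALPHABET
#' @format NULL
#' @export
CMP_ROLES <- c("Xaa", "Yaa", "Gly")

# Positions (1-based) holding each role given a frame offset and length.
# frame_offset in 0:2 is the 0-based index of the first Gly, so Gly sits at
# 1-based positions frame_offset + 1, +4, +7, ...
gly_positions <- function(frame_offset, length) {
  seq.int(frame_offset + 1L, length, by = 3L)
}

xaa_positions <- function(frame_offset, length) {
  p <- seq.int((frame_offset + 1L) %% 3L + 1L, length, by = 3L)
  p[(p - frame_offset - 1L) %% 3L == 1L]
}

yaa_positions <- function(frame_offset, length) {
  setdiff(seq_len(length), c(gly_positions(frame_offset, length),
                             xaa_positions(frame_offset, length)))
}

# Role of a single 1-based position under a frame offset.
position_role <- function(position, frame_offset) {
  r <- (position - 1L - frame_offset) %% 3L
  c("Gly", "Xaa", "Yaa")[r + 1L]
}

# Triplet index (0-based) of a position: each Xaa-Yaa-Gly unit ends at a Gly,
# and the three members of triplet t are Xaa, Yaa, Gly in order.  With p the
# 0-based position and f the frame offset:
#   Gly at p = f + 3t, Xaa at p = f - 2 + 3t, Yaa at p = f - 1 + 3t.
triplet_index <- function(position, frame_offset) {
  p0 <- position - 1L
  role <- position_role(position, frame_offset)
  offset <- c(Gly = 0L, Yaa = 1L, Xaa = 2L)[[role]]
  (p0 - frame_offset + offset) %/% 3L
}
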