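## Shared constants and small vector-geometry helpers. Loaded first.

## Fixed alphabets used everywhere: element channels in the order C,N,O,H,S,P
## and amino acids in alphabetical one-letter order. Changing either silently
## invalidates every trained checkpoint, so they are constants, not options.
ELEMENT_ORDER <- c("C", "N", "O", "H", "S", "P")

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Sander & Rost (1994) maximal accessible surface areas, A^2, used to
## normalise absolute per-residue SASA into relative SASA.
SANDER_ROST_MAX_ASA <- c(
  A = 106, R = 248, N = 157, D = 163, C = 135, Q = 198, E = 194,
  G = 84,  H = 184, I = 169, L = 164, K = 205, M = 188, F = 197,
  P = 136, S = 130, T = 142, W = 227, Y = 222, V = 142)

## Van der Waals radii (A) for the rolling-probe SASA; heavy atoms only.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

`%||%` <- function(a, b) if (is.null(a)) b else a

unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
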