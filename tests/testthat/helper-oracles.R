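# Independent brute-force oracles for the annealing detectors, built on a
# position-wise complementarity matrix rather than string searching.
#
# C[i, j] is TRUE when base i of `a` can pair with base j of `b` in an
# antiparallel duplex. A duplex of k contiguous pairs in which a[i..i+k-1]
# anneals to b[j..j+k-1] occupies the anti-diagonal cells
# (i, j+k-1), (i+1, j+k-2), ..., so match lengths are runs of TRUE along
# anti-diagonals (constant i + j).

.comp_matrix <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ac <- strsplit(toupper(a), "")[[1]]
  bc <- strsplit(toupper(b), "")[[1]]
  outer(unname(comp[ac]), bc, "==")
}

# longest anti-diagonal run anywhere: internal annealing
brute_internal_anneal <- function(a, b) {
  C <- .comp_matrix(a, b)
  na <- nrow(C); nb <- ncol(C)
  best <- 0L
  for (s in 2:(na + nb)) {
    i <- max(1L, s - nb):min(na, s - 1L)
    vals <- C[cbind(i, s - i)]
    r <- rle(vals)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  best
}

# longest run that includes a's 3'-terminal base: 3'-anchored annealing
brute_three_prime_anneal <- function(a, b) {
  C <- .comp_matrix(a, b)
  na <- nrow(C); nb <- ncol(C)
  best <- 0L
  for (j in seq_len(nb)) {
    k <- 0L
    while (na - k >= 1 && j + k <= nb && C[na - k, j + k]) k <- k + 1L
    best <- max(best, k)
  }
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Reference nearest-neighbor Tm values from Biopython's MeltingTemp module
# (an independently maintained implementation of the same published model).
tm_oracle_biopython <- function(seqs, sodium_mM = 115, oligo_nM = 1600) {
  infile <- tempfile(fileext = ".txt")
  writeLines(seqs, infile)
  script <- tempfile(fileext = ".py")
  writeLines(sprintf("
import sys
from Bio.SeqUtils import MeltingTemp as mt
from Bio.Seq import Seq
for line in open(sys.argv[1]):
    s = line.strip()
    if not s:
        continue
    selfc = s == str(Seq(s).reverse_complement())
    print(repr(mt.Tm_NN(s, nn_table=mt.DNA_NN3, Na=%f, dnac1=%f, dnac2=0,
                        saltcorr=5, selfcomp=selfc)))
", sodium_mM, oligo_nM), script)
  out <- system2("python", c(script, infile), stdout = TRUE)
  as.numeric(out)
}

let7a_record <- function() {
  list(name = "ssc-let-7a", raw_sequence = "TGAGGTAGTAGGTTGTATAGTT")
}
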