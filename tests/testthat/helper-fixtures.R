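## Small shared fixtures; everything is generated in code at test time.
px <- pixelExtractor()

smallFaces <- function(n = 3, seed = 1) makeFaces(n, seed = seed, size = 64)

pixelTable <- function(stim) extractFeatures(px, stim)

## A constant "activation table" built by hand for constructed-distance tests.
tableFromMatrix <- function(m, kind = "fc") {
  ActivationTable(data.frame(index = 0L, name = "L0", kind = kind,
                             stringsAsFactors = FALSE),
                  list(m), as.character(seq_len(nrow(m))))
}
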