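# Shared fixture builders. All phantom fields are generated in code at test
# time; seeds are fixed by the calling test.

# a standard single-phantom field comfortably inside the frame
stdPhantomField <- function(rnRadius = 20, peak = 255L, haloScale = 30,
                            background = 5L, noiseSd = 0, size = NULL,
                            seed = 1L, plateau = TRUE) {
  supp <- rnRadius + haloScale * sqrt(log(2 * (peak - background)))
  if (is.null(size)) size <- 2L * ceiling(supp) + 9L
  ctr <- (size + 1) / 2
  sp <- phantomSpec(center = c(ctr, ctr), rnRadius = rnRadius, peak = peak,
                    haloScale = haloScale, background = background,
                    plateau = plateau, noiseSd = noiseSd)
  c(renderField(list(sp), size, size, seed = seed), list(spec = sp))
}

# test-scale measurement config: min area 100 suits phantom RN radii >= 10 px
testConfig <- function(shorthand = "x55/15", ...) {
  parseThresholds(shorthand, minObjectArea = 100, ...)
}

# phantom parameters that realise a programmed class under RNx55/RN220:
# Ia saturating bright core, Ib pale core well below the 220 cut (margin
# >= 10 intensity units), II peak too dim for the RN threshold to exist
classPhantomSpec <- function(label, center, rnRadius = 15, haloScale = 20) {
  peak <- switch(label, Ia = 255L, Ib = 200L, II = 50L)
  phantomSpec(center, rnRadius = rnRadius, peak = peak,
              haloScale = haloScale, background = 5L, classIntent = label)
}

renderClassPhantom <- function(label, rnRadius = 15, haloScale = 20,
                               seed = 1L) {
  supp <- rnRadius + haloScale * sqrt(log(2 * 250))
  size <- 2L * ceiling(supp) + 9L
  ctr <- (size + 1) / 2
  renderField(list(classPhantomSpec(label, c(ctr, ctr), rnRadius, haloScale)),
              size, size, seed = seed)
}
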