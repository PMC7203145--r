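# Shared fixtures: tiny architecture specs, normalized slides and patch sets
# built from the phantom generator. Everything is seeded and built in code.

tinyGenSpec <- function(nStains = 3L)
  generatorSpec(levels = 2L, stemChannels = 8L, nStains = nStains)

tinyDiscSpec <- function(patchSize = 64L, nStains = 3L)
  discriminatorSpec(blocks = 3L, stemChannels = 8L, nStains = nStains,
                    patchSize = patchSize, fcHidden = 64L)

# Slide with both channels z-normalized over the tissue mask.
normalizedSlide <- function(sl) {
  af <- sl@af
  for (c in 1:2) af[, , c] <- normalizeSlide(af[, , c], sl@mask)
  new("SlidePair", af = af, target = sl@target, mask = sl@mask,
      stainWeights = sl@stainWeights)
}

# Small patch set drawn from a seeded dataset; patchSize must be divisible
# by 4 for the tiny generator.
smallPatchSet <- function(nSlides = 6L, seed = 3L, slideSize = 96L,
                          patchSize = 32L, stride = 32L - 8L) {
  ds <- makeStainDataset(nSlides = nSlides, seed = seed, size = slideSize)
  patches <- list()
  for (i in ds$manifest$slide[ds$manifest$split == "train"])
    patches <- c(patches,
                 extractPatches(normalizedSlide(ds$slides[[i]]),
                                size = patchSize, stride = stride,
                                minTissue = 0.2))
  patches
}

# Textured single-channel image for registration tests.
textureImage <- function(seed, size = 256L) {
  ph <- generatePhantom(seed = seed, height = size, width = size)
  ph@channels[, , 1] + ph@channels[, , 2]
}
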