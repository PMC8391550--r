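# shared fixture builders: everything is generated in code at test time

smallScene <- function(seed = 1L, size = 40L, variability = 1, ...) {
  sceneConfig(height = size, width = size, seed = seed,
              classModels = scaleVariability(defaultClassModels(), variability),
              subjectEffectSd = 0.02 * variability, ...)
}

smallCohort <- function(n = 3L, seed = 1L, size = 40L, variability = 1, ...) {
  makeCohort(smallScene(seed = seed, size = size, variability = variability, ...), n)
}

randomCube <- function(H = 8L, W = 8L, B = 100L, seed = 1L, subjectId = "T01") {
  set.seed(seed)
  HSICube(array(rnorm(H * W * B), dim = c(H, W, B)),
          wavelengthGrid(B), subjectId)
}
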