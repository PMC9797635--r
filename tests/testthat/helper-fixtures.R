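## Shared fixtures, built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, builder(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

tinyNoiseless <- function() {
  .cached("tinyNoiseless", function()
    makeFixture("tiny", ratio = 10, seed = 7L, noiseless = TRUE,
                jitterCv = 0))
}

tinyNoisy <- function() {
  .cached("tinyNoisy", function()
    makeFixture("tiny", ratio = 10, seed = 7L))
}

defaultGeom <- function() {
  .cached("defaultGeom", function() buildPhantom())
}

## Noiseless, jitter-free acquisition of the standard phantom at the given
## ratio (used to probe systematic, not stochastic, behavior).
defaultNoiselessAcq <- function(ratio = 10) {
  .cached(paste0("defaultNoiseless", ratio), function() {
    filled <- fillActivities(defaultGeom(), ratio, jitterCv = 0, seed = 1L)
    simulateSpect(filled$activity, acquisitionConfig(noiseless = TRUE),
                  filled$fill, id = sprintf("nl%02d", ratio))
  })
}

## Expected (noise-free) image of an arbitrary activity map under the
## default acquisition blur chain; used to decompose count origins.
blurChain <- function(activity, geometry, psf = 11, post = 6) {
  e <- gaussianSmooth3d(activity, psf, voxelSize(geometry))
  gaussianSmooth3d(e, post, voxelSize(geometry))
}

## The default 23-acquisition study quantified with all five methods;
## shared by the acceptance checks (simulated once).
acceptanceStudy <- function() {
  .cached("acceptanceStudy", function() {
    geom <- defaultGeom()
    acqs <- generateStudy(geom, masterSeed = 1L)
    results <- quantifyStudy(acqs, geom, voiSeed = 1L)
    list(geometry = geom, acquisitions = acqs, results = results,
         report = evaluateStudy(results))
  })
}
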