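# The default synthetic study is used by several end-to-end tests; run
# it once and share the result.
.runCache <- new.env(parent = emptyenv())

defaultRun <- function() {
    if (is.null(.runCache$run))
        .runCache$run <- suppressMessages(
            runPipeline(simulationConfig(seed = 1L)))
    .runCache$run
}
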