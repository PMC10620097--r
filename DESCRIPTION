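Package: metamerlab
Title: Model Metamer Synthesis and Evaluation for Staged Sensory Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Synthesizes model metamers, stimuli matched to the activations of a
    chosen stage of a staged differentiable sensory model, by constrained
    gradient descent on the input signal, and certifies each candidate against
    null distributions of activation-match metrics computed from random natural
    stimulus pairs. Includes a toy-model zoo (image and audio convolutional
    models with hand-written gradients and a simplified auditory filterbank
    front end), cross-model transfer analyses with permutation tests,
    permutation-based mixed-design ANOVAs and split-half reliability analyses
    for behavioral response tables, and noise-ceiling-corrected voxel-wise
    encoding and representational similarity analyses for stimulus-by-voxel
    response data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
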