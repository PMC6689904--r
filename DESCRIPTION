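Package: gestnet
Title: Gesture Sequence Coding and Permutation-Based Social Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking primate gestural communication to sociality.
    Segments time-stamped gesture event logs into single gestures, rapid
    sequences and persistence sequences using response-waiting timing rules;
    builds directed weighted dyadic matrices (proximity per party-hour,
    per-sequence-type and per-response-type communication rates, binary
    attribute similarity) from scan-sampled focal follows; and performs
    permutation inference on those matrices via QAP correlation, multiple
    regression QAP with Double-Dekker semi-partialling, and node-level
    permutation regression of degree centralities. Includes Cohen's kappa
    inter-coder reliability utilities and a synthetic fission-fusion data
    generator with planted dyad-level sociality effects for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
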