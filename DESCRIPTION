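Package: kngp
Title: Candidate Gene Prioritization on Weighted Knowledge Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate disease genes by propagating knowledge over a
    weighted network. Implements a random-walk-with-restart (PageRank with
    priors) model in which biological knowledge enters twice: pairwise
    knowledge (e.g. interaction confidence) as link weights that shape the
    transition matrix, and per-gene knowledge (e.g. annotation counts) as
    node weights that shape the restart prior. A scalar f trades off
    root-set membership against node-weight knowledge in the prior; f = 0
    uses node weights only and large f recovers the classic uniform-over-
    roots prior. Includes the leave-one-out ROC/AUC evaluation protocol
    used to select f, a restart-probability calibration sweep, and seeded
    generators for four complete weighted 1000-node benchmark networks
    with group-structured node and link weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
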