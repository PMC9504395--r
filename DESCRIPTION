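Package: opinionpulse
Title: Social Sensing of Vaccine Opinions from Geotagged Posts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Population-normalised engagement scoring and Bayesian net-
    sentiment estimation for geotagged social-media corpora. Implements a
    public engagement score (daily post volume divided by a sublinear power
    of population), a Dirichlet-multinomial model of three-class sentiment
    proportions with rolling informative priors built from the preceding
    week, credible intervals for the net sentiment score, keyword-lexicon
    topic tagging with bigram/trigram diagnostics, probabilistic surname-
    based race imputation from census-style distribution tables, and a
    synthetic geo-corpus generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
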