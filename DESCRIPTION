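Package: elicitopt
Title: Modeling and Optimization of Elicitor-Driven Paclitaxel Biosynthesis in Plant Cell Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Surrogate modeling and evolutionary optimization of secondary-metabolite
    yield in elicited plant cell suspension cultures. Generates synthetic factorial
    elicitation experiments (fungal cell-extract and culture-filtrate doses, elicitor
    adding day, harvest day) with known ground-truth response surfaces, fits backward-
    elimination multiple linear regression and a three-layer perceptron (tansig hidden,
    linear output) trained by full-batch back-propagation, selects the hidden-layer
    size and optimizes culture inputs with a real-coded genetic algorithm using
    roulette-wheel selection, ranks input importance by variable sensitivity ratios
    (VSE/VSR), and reports optima with blend-composition and elapsed-time arithmetic.
    Fitted perceptrons export to a portable JSON estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
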