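#!/usr/bin/env Rscript

# Step 2 — train and evaluate the polarity classifier.
#
# The pipeline's recommended mode takes polarity labels on input; this
# step shows the self-contained alternative. A Naive Bayes model is
# trained on a synthetic labelled corpus at partial vocabulary separation
# and evaluated on a held-out sample, then serialized for optional use by
# the pipeline (classifier_model config key).

suppressPackageStartupMessages(library(opinionpulse))

dir.create("results/model", recursive = TRUE, showWarnings = FALSE)

train <- generate_labeled_sentiment_corpus(600, vocab_separation = 0.6,
                                           seed = 301)
test <- generate_labeled_sentiment_corpus(200, vocab_separation = 0.6,
                                          seed = 302)
model <- train_nb(train$text, train$polarity)
pred <- classify_all(model, test$text)
acc <- mean(pred$polarity == test$polarity)
cat(sprintf("held-out accuracy at vocabulary separation 0.6: %.3f\n", acc))

by_class <- vapply(split(pred$polarity == test$polarity, test$polarity),
                   mean, numeric(1))
print(round(by_class, 3))

write_nb_model(model, "results/model/nb_polarity.json")
cat("model written to results/model/nb_polarity.json\n")
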