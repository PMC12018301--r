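// Sequential kernels for the hyperdimensional classifier: cosine-similarity
// prediction and the retraining (error-mitigation) passes of the training
// loop. Matrices are passed transposed (d x n, d x C) so each sample / class
// vector is a contiguous column. Encodings and class vectors hold integer
// values stored as doubles, so all updates below are exact.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Argmax of cosine similarity between sample column x and the C class
// columns; ties (and zero norms) resolve to the first class in order.
static int predict_one(const double *x, double xnormsq, const double *cls,
                       const double *cls_normsq, int d, int C) {
  int best = 0;
  double best_score = -HUGE_VAL;
  for (int c = 0; c < C; ++c) {
    double dot = 0.0;
    const double *v = cls + (size_t)c * d;
    for (int j = 0; j < d; ++j) dot += v[j] * x[j];
    double score;
    if (cls_normsq[c] > 0.0 && xnormsq > 0.0) {
      score = dot / std::sqrt(cls_normsq[c]);
    } else {
      score = 0.0;
    }
    if (score > best_score) {
      best_score = score;
      best = c;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector hd_predict_cpp(NumericMatrix enc_t, NumericMatrix class_t) {
  const int d = enc_t.nrow(), n = enc_t.ncol(), C = class_t.ncol();
  if (class_t.nrow() != d) stop("dimensionality mismatch between samples and class vectors");
  std::vector<double> cls_normsq(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      double v = class_t(j, c);
      s += v * v;
    }
    cls_normsq[c] = s;
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double *x = &enc_t(0, i);
    double xnormsq = 0.0;
    for (int j = 0; j < d; ++j) xnormsq += x[j] * x[j];
    out[i] = predict_one(x, xnormsq, &class_t(0, 0), cls_normsq.data(), d, C);
  }
  return out;
}

// Retraining: repeated passes over the training samples in dataset order.
// Within a pass each sample is predicted against the *current* (mutating)
// class vectors; a misclassified sample is subtracted from the wrongly
// predicted class vector and added to its true class vector. Error counts
// come from a full non-mutating evaluation before the first pass and after
// every pass; passes stop when the count repeats or after R passes.
// [[Rcpp::export]]
List hd_retrain_cpp(NumericMatrix enc_t, IntegerVector labels,
                    NumericMatrix class_t, int R) {
  const int d = enc_t.nrow(), n = enc_t.ncol(), C = class_t.ncol();
  if (class_t.nrow() != d) stop("dimensionality mismatch between samples and class vectors");
  if (labels.size() != n) stop("one label per sample required");
  NumericMatrix cls = clone(class_t);
  std::vector<double> cls_normsq(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      double v = cls(j, c);
      s += v * v;
    }
    cls_normsq[c] = s;
  }
  std::vector<double> xnormsq(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    const double *x = &enc_t(0, i);
    for (int j = 0; j < d; ++j) s += x[j] * x[j];
    xnormsq[i] = s;
  }

  auto evaluate = [&]() {
    int errors = 0;
    for (int i = 0; i < n; ++i) {
      int pred = predict_one(&enc_t(0, i), xnormsq[i], &cls(0, 0),
                             cls_normsq.data(), d, C);
      if (pred != labels[i]) ++errors;
    }
    return errors;
  };

  int prev = 0;  // sentinel: a zero-error model converges immediately
  int curr = evaluate();
  int iterations = 0;
  std::vector<int> history;
  history.push_back(curr);

  while (curr != prev && iterations < R) {
    for (int i = 0; i < n; ++i) {
      const double *x = &enc_t(0, i);
      // prediction with per-class dots kept for the incremental norm update
      int best = 0;
      double best_score = -HUGE_VAL;
      std::vector<double> dots(C);
      for (int c = 0; c < C; ++c) {
        double dot = 0.0;
        const double *v = &cls(0, c);
        for (int j = 0; j < d; ++j) dot += v[j] * x[j];
        dots[c] = dot;
        double score = (cls_normsq[c] > 0.0 && xnormsq[i] > 0.0)
                           ? dot / std::sqrt(cls_normsq[c])
                           : 0.0;
        if (score > best_score) {
          best_score = score;
          best = c;
        }
      }
      int truth = labels[i];
      if (best != truth) {
        double *wrong = &cls(0, best);
        double *right = &cls(0, truth);
        for (int j = 0; j < d; ++j) {
          wrong[j] -= x[j];
          right[j] += x[j];
        }
        cls_normsq[best] += xnormsq[i] - 2.0 * dots[best];
        cls_normsq[truth] += xnormsq[i] + 2.0 * dots[truth];
      }
    }
    ++iterations;
    prev = curr;
    curr = evaluate();
    history.push_back(curr);
  }

  return List::create(_["class_vectors_t"] = cls,
                      _["iterations"] = iterations,
                      _["final_errors"] = curr,
                      _["error_history"] = wrap(history));
}
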