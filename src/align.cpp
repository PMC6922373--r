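#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Semi-global (read fully aligned, reference overhangs free) affine-gap
// alignment, Gotoh three-state DP. Gap of length L scores
// gap_open + (L - 1) * gap_extend. Deterministic tie-breaking: aligned pair
// (match/mismatch) preferred over gaps, deletion (gap in read) over
// insertion (gap in reference), and gap extension preferred during
// traceback so equal-scoring gaps are left-shifted and contiguous.

static const int NEG = INT_MIN / 4;

struct Aln {
  int score;
  int ref_start;      // 0-based first reference position consumed
  std::string ops;    // 'M' aligned pair, 'D' ref base deleted from read, 'I' read base inserted
};

static Aln align_core(const std::string &read, const std::string &ref,
                      int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)read.size(), m = (int)ref.size();
  const int m1 = m + 1;
  std::vector<int> M((n + 1) * m1, NEG), X((n + 1) * m1, NEG),
      Y((n + 1) * m1, NEG), H((n + 1) * m1, NEG);

  for (int j = 0; j <= m; ++j) H[j] = 0;  // free reference prefix
  for (int i = 1; i <= n; ++i) {
    const char ri = read[i - 1];
    int *Mi = &M[i * m1], *Xi = &X[i * m1], *Yi = &Y[i * m1], *Hi = &H[i * m1];
    const int *Hp = &H[(i - 1) * m1], *Yp = &Y[(i - 1) * m1];
    // column 0: read prefix hangs over the reference start as an insertion run
    Yi[0] = std::max(Hp[0] + gap_open, Yp[0] + gap_extend);
    Hi[0] = Yi[0];
    int xleft = NEG, hleft = Hi[0];
    for (int j = 1; j <= m; ++j) {
      const int s = (ri == ref[j - 1]) ? match : mismatch;
      const int mij = Hp[j - 1] + s;
      const int xij = std::max(hleft + gap_open, xleft + gap_extend);
      const int yij = std::max(Hp[j] + gap_open, Yp[j] + gap_extend);
      int h = mij;
      if (xij > h) h = xij;
      if (yij > h) h = yij;
      Mi[j] = mij; Xi[j] = xij; Yi[j] = yij; Hi[j] = h;
      xleft = xij; hleft = h;
    }
  }

  // free reference suffix: best score over the final read row; leftmost end
  const int *Hn = &H[n * m1];
  int best = NEG, jend = 0;
  for (int j = 0; j <= m; ++j)
    if (Hn[j] > best) { best = Hn[j]; jend = j; }

  // traceback; state preference M > X > Y at equal score
  auto at = [m1](int i, int j) { return i * m1 + j; };
  std::string ops;
  int i = n, j = jend;
  char state;
  if (M[at(i, j)] == best) state = 'M';
  else if (X[at(i, j)] == best) state = 'X';
  else state = 'Y';
  while (i > 0) {
    if (state == 'M') {
      ops.push_back('M');
      int prev = H[at(i - 1, j - 1)];
      --i; --j;
      if (i == 0) break;
      if (M[at(i, j)] == prev) state = 'M';
      else if (X[at(i, j)] == prev) state = 'X';
      else state = 'Y';
    } else if (state == 'X') {
      ops.push_back('D');
      // prefer extension at equal score (left-shifts the gap)
      if (X[at(i, j)] == X[at(i, j - 1)] + gap_extend && X[at(i, j - 1)] > NEG) {
        --j;
      } else {
        int prev = H[at(i, j - 1)];
        --j;
        if (M[at(i, j)] == prev) state = 'M';
        else if (X[at(i, j)] == prev) state = 'X';
        else state = 'Y';
      }
    } else { // Y
      ops.push_back('I');
      if (Y[at(i, j)] == Y[at(i - 1, j)] + gap_extend && Y[at(i - 1, j)] > NEG) {
        --i;
        if (i == 0) break;
      } else {
        int prev = H[at(i - 1, j)];
        --i;
        if (i == 0) break;
        if (M[at(i, j)] == prev) state = 'M';
        else if (X[at(i, j)] == prev) state = 'X';
        else state = 'Y';
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  Aln out;
  out.score = best;
  out.ref_start = j;
  out.ops = ops;
  return out;
}

// net indel (insertions minus deletions) for gap runs overlapping the
// half-open reference window [lo, hi); whole run counted when it overlaps
static int net_indel_in_window(const Aln &a, int lo, int hi) {
  int r = a.ref_start, net = 0;
  size_t k = 0;
  const std::string &ops = a.ops;
  while (k < ops.size()) {
    char op = ops[k];
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == op) ++k2;
    int len = (int)(k2 - k);
    if (op == 'M') {
      r += len;
    } else if (op == 'D') {
      if (r < hi && r + len > lo) net -= len;
      r += len;
    } else { // 'I' at inter-base position r
      if (r >= lo && r <= hi) net += len;
    }
    k = k2;
  }
  return net;
}

// [[Rcpp::export]]
List align_read_cpp(std::string read, std::string ref, int match, int mismatch,
                    int gap_open, int gap_extend) {
  if (read.empty()) stop("read must be non-empty");
  Aln a = align_core(read, ref, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = a.score, _["ref_start"] = a.ref_start,
                      _["ops"] = a.ops);
}

// Batch net-indel caller. Each read is first anchored by an exact 24-mer
// prefix hit in the reference and aligned within a +/- 60 bp band around
// it (exactly equivalent to the full DP whenever the optimal alignment
// lies inside the band, which a spanning amplicon read's does); reads
// whose prefix has no exact hit fall back to the full-width DP.
// [[Rcpp::export]]
IntegerVector align_reads_net_cpp(CharacterVector reads, std::string ref,
                                  int match, int mismatch, int gap_open,
                                  int gap_extend, int win_lo, int win_hi) {
  const int n = reads.size();
  const int m = (int)ref.size();
  const int margin = 60;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    const int L = (int)rd.size();
    int k = std::min(24, L);
    size_t pos = ref.find(rd.substr(0, k));
    bool banded = pos != std::string::npos &&
                  ref.find(rd.substr(0, k), pos + 1) == std::string::npos;
    Aln a;
    int lo = 0;
    if (banded) {
      lo = std::max(0, (int)pos - margin);
      int hi = std::min(m, (int)pos + L + margin);
      a = align_core(rd, ref.substr(lo, hi - lo), match, mismatch, gap_open,
                     gap_extend);
      a.ref_start += lo;
    } else {
      a = align_core(rd, ref, match, mismatch, gap_open, gap_extend);
    }
    out[i] = net_indel_in_window(a, win_lo, win_hi);
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
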