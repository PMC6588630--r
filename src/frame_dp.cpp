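// Frame-aware local alignment of a protein query against a DNA segment.
// Dynamic programming over (query residue i, DNA nucleotide j) with moves:
//   match:    consume 3 nt for one residue, BLOSUM score of the codon
//   fs1/fs2:  consume 2 or 4 nt for one residue (frameshift penalty,
//             residue unscored)
//   gap_q:    skip one query residue (gap in DNA)
//   gap_d:    skip one codon of DNA (gap in query)
// Alignments are local (scores clamped at 0). In-frame stop codons score
// a fixed penalty and are reported as nonsense events on the traceback.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List frame_dp(IntegerVector aa_at,   // 1-based codon start -> aa index (0..24), -1 stop, -2 invalid
              IntegerVector query,   // query residue indices (0..24)
              IntegerMatrix submat,  // 25x25 substitution scores
              int stop_score,
              int fs_penalty,
              int gap_penalty) {
  const int n = aa_at.size();        // DNA length (codon starts valid up to n-2)
  const int m = query.size();
  // H indexed by [i][j]: query residues consumed = i, DNA consumed up to j nt
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<unsigned char>> B(m + 1,
      std::vector<unsigned char>(n + 1, 0)); // 0 stop, 1 m3, 2 fs2, 3 fs4, 4 gq, 5 gd
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int qi = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      int sc = 0; unsigned char mv = 0;
      if (j >= 3) {
        int a = aa_at[j - 3];        // codon starting at nt j-2 (1-based)
        int s = (a == -1) ? stop_score : (a < 0 ? -1 : submat(qi, a));
        int v = H[i - 1][j - 3] + s;
        if (v > sc) { sc = v; mv = 1; }
      }
      if (j >= 2) {
        int v = H[i - 1][j - 2] - fs_penalty;
        if (v > sc) { sc = v; mv = 2; }
      }
      if (j >= 4) {
        int a = aa_at[j - 3];
        int s = (a == -1) ? stop_score : (a < 0 ? -1 : submat(qi, a));
        int v = H[i - 1][j - 4] - fs_penalty + s;
        if (v > sc) { sc = v; mv = 3; }
      }
      {
        int v = H[i - 1][j] - gap_penalty;
        if (v > sc) { sc = v; mv = 4; }
      }
      if (j >= 3) {
        int v = H[i][j - 3] - gap_penalty;
        if (v > sc) { sc = v; mv = 5; }
      }
      H[i][j] = sc; B[i][j] = mv;
      if (sc > best) { best = sc; bi = i; bj = j; }
    }
  }
  // traceback
  std::vector<int> ev_type;   // 1 nonsense, 2 frameshift
  std::vector<int> ev_pos;    // DNA position (1-based codon start / shift point)
  std::vector<int> q_idx, d_pos; // matched residue -> codon start (0 if unscored)
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H[i][j] > 0) {
    unsigned char mv = B[i][j];
    if (mv == 0) break;
    if (mv == 1) {
      int a = aa_at[j - 3];
      if (a == -1) { ev_type.push_back(1); ev_pos.push_back(j - 2); }
      q_idx.push_back(i); d_pos.push_back(j - 2);
      i -= 1; j -= 3;
    } else if (mv == 2) {
      ev_type.push_back(2); ev_pos.push_back(j - 1);
      q_idx.push_back(i); d_pos.push_back(0);
      i -= 1; j -= 2;
    } else if (mv == 3) {
      int a = aa_at[j - 3];
      if (a == -1) { ev_type.push_back(1); ev_pos.push_back(j - 2); }
      ev_type.push_back(2); ev_pos.push_back(j - 3);
      q_idx.push_back(i); d_pos.push_back(j - 2);
      i -= 1; j -= 4;
    } else if (mv == 4) {
      i -= 1;
    } else {
      j -= 3;
    }
  }
  std::reverse(ev_type.begin(), ev_type.end());
  std::reverse(ev_pos.begin(), ev_pos.end());
  std::reverse(q_idx.begin(), q_idx.end());
  std::reverse(d_pos.begin(), d_pos.end());
  return List::create(_["score"] = best,
                      _["q_start"] = i + 1, _["q_end"] = bi,
                      _["d_start"] = j + 1, _["d_end"] = bj,
                      _["event_type"] = ev_type, _["event_pos"] = ev_pos,
                      _["q_idx"] = q_idx, _["d_pos"] = d_pos);
}
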