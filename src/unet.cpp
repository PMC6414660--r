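// Modified 3D U-net for renal parenchyma segmentation, implemented from
// scratch on RcppArmadillo (single-precision, batch size 1).
//
// Feature maps are (channels x voxels) matrices over a column-major
// (x,y,z) lattice carrying a one-voxel zero halo on every face. With the
// halo, each 3x3x3 "same" convolution is a sum of 27 accumulating GEMMs
// on contiguous column-offset views (no shifted copies, no im2col); halo
// columns are re-zeroed after every convolution so they always represent
// zero padding. 2x2x2 stride-2 convolutions and transposed convolutions
// gather/scatter between the padded lattices of adjacent levels.
// Backward passes are hand-derived adjoints; the optimizer is ADAM with
// bias correction and an epsilon-zero guard (zero update where the second
// moment is exactly zero).
//
// Topology (levels L, channels c_l = base * 2^l):
//   stem: 3x3x3 conv, 1 -> c_0
//   contraction level l = 0..L-2:
//     pre-activation residual block (lrelu -> 3x3x3 -> lrelu -> 3x3x3, + identity)
//     3D spatial dropout -> skip connection source
//     2x2x2 stride-2 conv c_l -> c_{l+1}
//     element-wise sum junction: x = s + 3x3x3conv(lrelu(s))
//   bottom (level L-1): residual block + spatial dropout
//   expansion level l = L-2..0:
//     2x2x2 transposed conv c_{l+1} -> c_l, concatenation with skip,
//     lrelu -> 3x3x3 conv -> lrelu -> 1x1x1 conv
//   head: 3x3x3 conv after the top stage, then element-wise sum of the
//     last three expansion-path conv outputs after 1x1x1 projection to one
//     channel, then sigmoid. The head projections start with a negative
//     bias so the initial foreground probability sits near the prevalence
//     rather than 0.5 (standard segmentation initialization).
// Ablation flags: use_residual_blocks=FALSE collapses each block to a
// single lrelu->3x3x3 conv; use_elementwise_sum=FALSE removes the sum
// junctions and the two extra head projections; use_skip_connections=FALSE
// removes the concatenations. Each removal strictly reduces parameters.
#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

struct Dims {
  int nx, ny, nz;        // interior (true volume) dims
  int px() const { return nx + 2; }
  int py() const { return ny + 2; }
  int pz() const { return nz + 2; }
  uword npad() const { return (uword)px() * py() * pz(); }
  // padded column index of interior voxel (x, y, z), 0-based interior coords
  uword id(int x, int y, int z) const {
    return (uword)(x + 1) + (uword)px() * ((uword)(y + 1) + (uword)py() * (z + 1));
  }
};

static void zero_halo(fmat &X, const Dims &d) {
  const int px = d.px(), py = d.py(), pz = d.pz();
  for (int z = 0; z < pz; ++z)
    for (int y = 0; y < py; ++y) {
      const uword base = (uword)px * ((uword)y + (uword)py * z);
      if (z == 0 || z == pz - 1 || y == 0 || y == py - 1) {
        X.cols(base, base + px - 1).zeros();
      } else {
        X.col(base).zeros();
        X.col(base + px - 1).zeros();
      }
    }
}

struct Conv {
  std::string name;
  int kind;  // 3: 3x3x3 same, 2: 2x2x2 stride-2 down, -2: 2x2x2 transposed up, 1: 1x1x1
  int cin, cout;
  fmat W;  // cout x (K*cin), offset-major blocks
  fvec b;
  fmat gW, mW, vW;
  fvec gb, mb, vb;
  int K() const { return kind == 3 ? 27 : (kind == 1 ? 1 : 8); }
};

static const int OFF3[27][3] = {
    {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
    {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
    {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}};
static const int OFF2[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};

// non-owning view over a contiguous column range
static inline fmat view_cols(const fmat &X, uword a, uword len) {
  return fmat(const_cast<float *>(X.colptr(a)), X.n_rows, len, false, true);
}

// nx,ny,nz of `d` are the dims of the conv INPUT grid (for kind -2, the
// coarse input grid). All matrices live on padded lattices.
static fmat conv_fwd(const Conv &c, const fmat &X, const Dims &d) {
  if (c.kind == 1) {
    fmat Y = c.W * X;
    Y.each_col() += c.b;
    zero_halo(Y, d);
    return Y;
  }
  if (c.kind == 3) {
    const uword N = d.npad();
    fmat Y(c.cout, N);
    Y.each_col() = c.b;
    for (int k = 0; k < 27; ++k) {
      const long o = OFF3[k][0] + (long)d.px() * OFF3[k][1] +
                     (long)d.px() * d.py() * OFF3[k][2];
      const uword a = o < 0 ? (uword)(-o) : 0;
      const uword b = o > 0 ? N - 1 - (uword)o : N - 1;
      fmat dst(Y.colptr(a), c.cout, b - a + 1, false, true);
      dst += c.W.cols((uword)k * c.cin, (uword)(k + 1) * c.cin - 1) *
             view_cols(X, a + o, b - a + 1);
    }
    zero_halo(Y, d);
    return Y;
  }
  const Dims dc = {d.nx / 2, d.ny / 2, d.nz / 2};  // coarse dims for kind 2
  if (c.kind == 2) {
    const uword nc = (uword)dc.nx * dc.ny * dc.nz;
    fmat acc(c.cout, nc);
    acc.each_col() = c.b;
    fmat S(c.cin, nc);
    for (int k = 0; k < 8; ++k) {
      uword j = 0;
      for (int z = 0; z < dc.nz; ++z)
        for (int y = 0; y < dc.ny; ++y)
          for (int x = 0; x < dc.nx; ++x, ++j)
            S.col(j) = X.col(d.id(2 * x + OFF2[k][0], 2 * y + OFF2[k][1],
                                  2 * z + OFF2[k][2]));
      acc += c.W.cols((uword)k * c.cin, (uword)(k + 1) * c.cin - 1) * S;
    }
    fmat Y(c.cout, dc.npad(), arma::fill::zeros);
    uword j = 0;
    for (int z = 0; z < dc.nz; ++z)
      for (int y = 0; y < dc.ny; ++y)
        for (int x = 0; x < dc.nx; ++x, ++j)
          Y.col(dc.id(x, y, z)) = acc.col(j);
    return Y;
  }
  // kind == -2: transposed, coarse input dims d -> fine output 2x dims
  const Dims df = {2 * d.nx, 2 * d.ny, 2 * d.nz};
  fmat Y(c.cout, df.npad(), arma::fill::zeros);
  for (int k = 0; k < 8; ++k) {
    const fmat Wk = c.W.cols((uword)k * c.cin, (uword)(k + 1) * c.cin - 1);
    fmat Yk = Wk * X;  // over all coarse cols; halo cols are zero
    for (int z = 0; z < d.nz; ++z)
      for (int y = 0; y < d.ny; ++y)
        for (int x = 0; x < d.nx; ++x)
          Y.col(df.id(2 * x + OFF2[k][0], 2 * y + OFF2[k][1], 2 * z + OFF2[k][2])) =
              Yk.col(d.id(x, y, z));
  }
  Y.each_col() += c.b;
  zero_halo(Y, df);
  return Y;
}

// dY must have a zero halo; returns dX (zero halo) and accumulates grads.
static fmat conv_bwd(Conv &c, const fmat &X, const fmat &dY, const Dims &d) {
  c.gb += arma::sum(dY, 1);
  if (c.kind == 1) {
    c.gW += dY * X.t();
    fmat dX = c.W.t() * dY;
    zero_halo(dX, d);
    return dX;
  }
  if (c.kind == 3) {
    const uword N = d.npad();
    fmat dX(X.n_rows, N, arma::fill::zeros);
    for (int k = 0; k < 27; ++k) {
      const long o = OFF3[k][0] + (long)d.px() * OFF3[k][1] +
                     (long)d.px() * d.py() * OFF3[k][2];
      const uword a = o < 0 ? (uword)(-o) : 0;
      const uword b = o > 0 ? N - 1 - (uword)o : N - 1;
      const uword len = b - a + 1;
      const fmat dYv = view_cols(dY, a, len);
      c.gW.cols((uword)k * c.cin, (uword)(k + 1) * c.cin - 1) +=
          dYv * view_cols(X, a + o, len).t();
      fmat dXv(dX.colptr(a + o), c.cin, len, false, true);
      dXv += c.W.cols((uword)k * c.cin, (uword)(k + 1) * c.cin - 1).t() * dYv;
    }
    zero_halo(dX, d);
    return dX;
  }
  const Dims dc = {d.nx / 2, d.ny / 2, d.nz / 2};
  if (c.kind == 2) {
    const uword nc = (uword)dc.nx * dc.ny * dc.nz;
    fmat dYi(c.cout, nc);
    {
      uword j = 0;
      for (int z = 0; z < dc.nz; ++z)
        for (int y = 0; y < dc.ny; ++y)
          for (int x = 0; x < dc.nx; ++x, ++j)
            dYi.col(j) = dY.col(dc.id(x, y, z));
    }
    fmat dX(X.n_rows, X.n_cols, arma::fill::zeros);
    fmat S(c.cin, nc);
    for (int k = 0; k < 8; ++k) {
      uword j = 0;
      for (int z = 0; z < dc.nz; ++z)
        for (int y = 0; y < dc.ny; ++y)
          for (int x = 0; x < dc.nx; ++x, ++j)
            S.col(j) = X.col(d.id(2 * x + OFF2[k][0], 2 * y + OFF2[k][1],
                                  2 * z + OFF2[k][2]));
      c.gW.cols((uword)k * c.cin, (uword)(k + 1) * c.cin - 1) += dYi * S.t();
      fmat G = c.W.cols((uword)k * c.cin, (uword)(k + 1) * c.cin - 1).t() * dYi;
      uword j2 = 0;
      for (int z = 0; z < dc.nz; ++z)
        for (int y = 0; y < dc.ny; ++y)
          for (int x = 0; x < dc.nx; ++x, ++j2)
            dX.col(d.id(2 * x + OFF2[k][0], 2 * y + OFF2[k][1],
                        2 * z + OFF2[k][2])) += G.col(j2);
    }
    return dX;
  }
  // kind == -2
  const Dims df = {2 * d.nx, 2 * d.ny, 2 * d.nz};
  fmat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  for (int k = 0; k < 8; ++k) {
    fmat Gk(c.cout, X.n_cols, arma::fill::zeros);
    for (int z = 0; z < d.nz; ++z)
      for (int y = 0; y < d.ny; ++y)
        for (int x = 0; x < d.nx; ++x)
          Gk.col(d.id(x, y, z)) =
              dY.col(df.id(2 * x + OFF2[k][0], 2 * y + OFF2[k][1],
                           2 * z + OFF2[k][2]));
    c.gW.cols((uword)k * c.cin, (uword)(k + 1) * c.cin - 1) += Gk * X.t();
    dX += c.W.cols((uword)k * c.cin, (uword)(k + 1) * c.cin - 1).t() * Gk;
  }
  zero_halo(dX, d);
  return dX;
}

static fmat lrelu(const fmat &X, float a) {
  fmat Y = X;
  Y.for_each([a](float &v) { if (v < 0) v *= a; });
  return Y;
}
static fmat lrelu_deriv_masked(const fmat &Xpre, float a) {
  // derivative at the pre-activation; halo entries are zero in Xpre and
  // get derivative `a`, but every gradient they multiply is halo-zeroed
  // downstream, so no special-casing is needed
  fmat D(Xpre.n_rows, Xpre.n_cols);
  for (uword i = 0; i < Xpre.n_elem; ++i) D(i) = Xpre(i) > 0 ? 1.0f : a;
  return D;
}

struct UNet {
  int levels, base;
  float slope, drop, dice_eps;
  bool residual, esum, skips;
  std::vector<Conv> convs;
  std::map<std::string, int> idx;
  long step = 0;

  int ch(int l) const { return base << l; }
  Conv &get(const std::string &n) { return convs[idx.at(n)]; }

  void add(const std::string &n, int kind, int cin, int cout) {
    Conv c;
    c.name = n; c.kind = kind; c.cin = cin; c.cout = cout;
    const int K = c.K();
    const int fan_in = K * cin;
    const double sd = std::sqrt(2.0 / (fan_in * (1.0 + slope * slope)));
    c.W.set_size(cout, (uword)K * cin);
    for (uword i = 0; i < c.W.n_elem; ++i) c.W(i) = (float)(R::norm_rand() * sd);
    c.b.zeros(cout);
    c.gW.zeros(arma::size(c.W)); c.mW.zeros(arma::size(c.W)); c.vW.zeros(arma::size(c.W));
    c.gb.zeros(cout); c.mb.zeros(cout); c.vb.zeros(cout);
    idx[n] = (int)convs.size();
    convs.push_back(std::move(c));
  }

  UNet(int levels_, int base_, double slope_, double drop_, bool residual_,
       bool esum_, bool skips_, double dice_eps_)
      : levels(levels_), base(base_), slope((float)slope_), drop((float)drop_),
        dice_eps((float)dice_eps_), residual(residual_), esum(esum_), skips(skips_) {
    add("stem", 3, 1, ch(0));
    for (int l = 0; l < levels; ++l) {
      add("rbA" + std::to_string(l), 3, ch(l), ch(l));
      if (residual) add("rbB" + std::to_string(l), 3, ch(l), ch(l));
    }
    for (int l = 0; l < levels - 1; ++l) {
      add("down" + std::to_string(l), 2, ch(l), ch(l + 1));
      if (esum) add("post" + std::to_string(l), 3, ch(l + 1), ch(l + 1));
      add("up" + std::to_string(l), -2, ch(l + 1), ch(l));
      add("decC3" + std::to_string(l), 3, skips ? 2 * ch(l) : ch(l), ch(l));
      add("decC1" + std::to_string(l), 1, ch(l), ch(l));
    }
    add("headC3", 3, ch(0), ch(0));
    add("projC", 1, ch(0), 1);
    if (esum) {
      add("projA", 1, ch(0), 1);
      add("projB", 1, ch(0), 1);
    }
    const float hb = esum ? -1.0f : -3.0f;
    get("projC").b.fill(hb);
    if (esum) { get("projA").b.fill(hb); get("projB").b.fill(hb); }
  }
};

struct Cache {
  std::vector<Dims> g;                       // per-level interior dims
  fmat X0;
  std::vector<fmat> xin, a1, z1, a2;         // per level (block internals)
  std::vector<fvec> dmask;                   // dropout channel masks
  std::vector<fmat> hd;                      // block output after dropout
  std::vector<fmat> s, s_lr;                 // down outputs, lrelu(s)
  std::vector<fmat> cat, cat_lr, a, a_lr, bout;  // expansion per l
  fmat b0_lr, cvol, logits, p;
};

static void forward(UNet &net, const fmat &X0, const Dims &d0, bool train,
                    Cache &K) {
  const int L = net.levels;
  K.g.resize(L);
  for (int l = 0; l < L; ++l)
    K.g[l] = {d0.nx >> l, d0.ny >> l, d0.nz >> l};
  K.xin.resize(L); K.a1.resize(L); K.z1.resize(L); K.a2.resize(L);
  K.dmask.resize(L); K.hd.resize(L);
  K.s.resize(L); K.s_lr.resize(L);
  K.cat.resize(L); K.cat_lr.resize(L); K.a.resize(L); K.a_lr.resize(L);
  K.bout.resize(L);
  K.X0 = X0;
  fmat x = conv_fwd(net.get("stem"), X0, d0);
  for (int l = 0; l < L; ++l) {
    const Dims &gd = K.g[l];
    K.xin[l] = x;
    K.a1[l] = lrelu(x, net.slope);
    fmat h;
    if (net.residual) {
      K.z1[l] = conv_fwd(net.get("rbA" + std::to_string(l)), K.a1[l], gd);
      K.a2[l] = lrelu(K.z1[l], net.slope);
      h = x + conv_fwd(net.get("rbB" + std::to_string(l)), K.a2[l], gd);
    } else {
      h = conv_fwd(net.get("rbA" + std::to_string(l)), K.a1[l], gd);
    }
    // 3D spatial dropout: whole feature-map channels
    fvec mask(h.n_rows, arma::fill::ones);
    if (train && net.drop > 0) {
      for (uword c = 0; c < mask.n_elem; ++c)
        mask(c) = (R::unif_rand() < net.drop) ? 0.0f : 1.0f / (1.0f - net.drop);
      h.each_col() %= mask;
    }
    K.dmask[l] = mask;
    K.hd[l] = h;
    if (l < L - 1) {
      fmat sdown = conv_fwd(net.get("down" + std::to_string(l)), h, gd);
      K.s[l] = sdown;
      if (net.esum) {
        K.s_lr[l] = lrelu(sdown, net.slope);
        x = sdown + conv_fwd(net.get("post" + std::to_string(l)), K.s_lr[l],
                             K.g[l + 1]);
      } else {
        x = sdown;
      }
    }
  }
  // expansion
  fmat xe = K.hd[L - 1];
  for (int l = L - 2; l >= 0; --l) {
    fmat u = conv_fwd(net.get("up" + std::to_string(l)), xe, K.g[l + 1]);
    fmat cat = net.skips ? arma::join_cols(u, K.hd[l]) : u;
    K.cat[l] = cat;
    K.cat_lr[l] = lrelu(cat, net.slope);
    K.a[l] = conv_fwd(net.get("decC3" + std::to_string(l)), K.cat_lr[l], K.g[l]);
    K.a_lr[l] = lrelu(K.a[l], net.slope);
    K.bout[l] = conv_fwd(net.get("decC1" + std::to_string(l)), K.a_lr[l], K.g[l]);
    xe = K.bout[l];
  }
  K.b0_lr = lrelu(K.bout[0], net.slope);
  K.cvol = conv_fwd(net.get("headC3"), K.b0_lr, d0);
  fmat logits = conv_fwd(net.get("projC"), K.cvol, d0);
  if (net.esum) {
    logits += conv_fwd(net.get("projA"), K.a[0], d0);
    logits += conv_fwd(net.get("projB"), K.bout[0], d0);
  }
  K.logits = logits;
  K.p = 1.0f / (1.0f + arma::exp(-logits));
  zero_halo(K.p, d0);  // probabilities are meaningful on the interior only
}

// soft-Dice over interior columns; p and t are padded with zero halos
static double dice_loss(const fmat &p, const fmat &t, float eps, fmat *dp,
                        const Dims &d) {
  const double S = arma::dot(p, t);
  const double P = arma::accu(p);
  const double T = arma::accu(t);
  const double D = P + T + eps;
  const double num = 2.0 * S + eps;
  const double loss = 1.0 - num / D;
  if (dp) {
    *dp = fmat(p.n_rows, p.n_cols);
    for (uword i = 0; i < p.n_elem; ++i)
      (*dp)(i) = (float)(-(2.0 * t(i) * D - num) / (D * D));
    zero_halo(*dp, d);
  }
  return loss;
}

static void zero_grads(UNet &net) {
  for (Conv &c : net.convs) { c.gW.zeros(); c.gb.zeros(); }
}

static void backward(UNet &net, Cache &K, const fmat &dp) {
  const int L = net.levels;
  const Dims &d0 = K.g[0];
  fmat dlogits = dp % K.p % (1.0f - K.p);  // halo zero via dp
  // head
  fmat dc = conv_bwd(net.get("projC"), K.cvol, dlogits, d0);
  fmat da0_head, db0_head;
  if (net.esum) {
    da0_head = conv_bwd(net.get("projA"), K.a[0], dlogits, d0);
    db0_head = conv_bwd(net.get("projB"), K.bout[0], dlogits, d0);
  }
  fmat db0_lr = conv_bwd(net.get("headC3"), K.b0_lr, dc, d0);
  fmat dx = db0_lr % lrelu_deriv_masked(K.bout[0], net.slope);
  if (net.esum) dx += db0_head;
  zero_halo(dx, d0);
  // expansion stages, fine -> coarse
  std::vector<fmat> dskip(L);
  for (int l = 0; l <= L - 2; ++l) {
    const Dims &gd = K.g[l];
    fmat da_lr = conv_bwd(net.get("decC1" + std::to_string(l)), K.a_lr[l], dx, gd);
    fmat da = da_lr % lrelu_deriv_masked(K.a[l], net.slope);
    if (l == 0 && net.esum) da += da0_head;
    zero_halo(da, gd);
    fmat dcat_lr = conv_bwd(net.get("decC3" + std::to_string(l)), K.cat_lr[l],
                            da, gd);
    fmat dcat = dcat_lr % lrelu_deriv_masked(K.cat[l], net.slope);
    zero_halo(dcat, gd);
    const int cl = net.ch(l);
    fmat du = dcat.rows(0, cl - 1);
    if (net.skips) dskip[l] = dcat.rows(cl, 2 * cl - 1);
    const fmat &exin = (l == L - 2) ? K.hd[L - 1] : K.bout[l + 1];
    dx = conv_bwd(net.get("up" + std::to_string(l)), exin, du, K.g[l + 1]);
  }
  // contraction, bottom -> top; dx currently holds grad at hd[L-1]
  fmat dhd = dx;
  for (int l = L - 1; l >= 0; --l) {
    const Dims &gd = K.g[l];
    if (l < L - 1 && net.skips && dskip[l].n_elem > 0) dhd += dskip[l];
    fmat dh = dhd;
    dh.each_col() %= K.dmask[l];
    fmat dxin;
    if (net.residual) {
      fmat da2 = conv_bwd(net.get("rbB" + std::to_string(l)), K.a2[l], dh, gd);
      fmat dz1 = da2 % lrelu_deriv_masked(K.z1[l], net.slope);
      zero_halo(dz1, gd);
      fmat da1 = conv_bwd(net.get("rbA" + std::to_string(l)), K.a1[l], dz1, gd);
      dxin = dh + da1 % lrelu_deriv_masked(K.xin[l], net.slope);
    } else {
      fmat da1 = conv_bwd(net.get("rbA" + std::to_string(l)), K.a1[l], dh, gd);
      dxin = da1 % lrelu_deriv_masked(K.xin[l], net.slope);
    }
    zero_halo(dxin, gd);
    if (l == 0) {
      conv_bwd(net.get("stem"), K.X0, dxin, gd);
    } else {
      fmat ds;
      if (net.esum) {
        fmat ds2 = conv_bwd(net.get("post" + std::to_string(l - 1)),
                            K.s_lr[l - 1], dxin, gd);
        ds = dxin + ds2 % lrelu_deriv_masked(K.s[l - 1], net.slope);
        zero_halo(ds, gd);
      } else {
        ds = dxin;
      }
      dhd = conv_bwd(net.get("down" + std::to_string(l - 1)), K.hd[l - 1], ds,
                     K.g[l - 1]);
    }
  }
}

static void adam_step(UNet &net, double lr, double b1, double b2, double eps) {
  net.step += 1;
  const double bc1 = 1.0 - std::pow(b1, (double)net.step);
  const double bc2 = 1.0 - std::pow(b2, (double)net.step);
  for (Conv &c : net.convs) {
    c.mW = (float)b1 * c.mW + (float)(1 - b1) * c.gW;
    c.vW = (float)b2 * c.vW + (float)(1 - b2) * arma::square(c.gW);
    c.mb = (float)b1 * c.mb + (float)(1 - b1) * c.gb;
    c.vb = (float)b2 * c.vb + (float)(1 - b2) * arma::square(c.gb);
    fmat dW = (c.mW / (float)bc1) / (arma::sqrt(c.vW / (float)bc2) + (float)eps);
    dW.replace(arma::datum::nan, 0.0f);
    fvec db = (c.mb / (float)bc1) / (arma::sqrt(c.vb / (float)bc2) + (float)eps);
    db.replace(arma::datum::nan, 0.0f);
    c.W -= (float)lr * dW;
    c.b -= (float)lr * db;
  }
}

static void check_dims(const UNet &net, IntegerVector dim) {
  const int f = 1 << (net.levels - 1);
  const char *ax = "xyz";
  for (int i = 0; i < 3; ++i)
    if (dim[i] % f != 0)
      stop("input shape axis '%c' (%d) is not divisible by 2^(levels-1) = %d",
           ax[i], (int)dim[i], f);
}

// embed an R volume (interior, column-major) into a padded 1-channel row
static fmat pad_row(NumericVector x, const Dims &d) {
  fmat X(1, d.npad(), arma::fill::zeros);
  R_xlen_t i = 0;
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int xx = 0; xx < d.nx; ++xx, ++i)
        X(0, d.id(xx, y, z)) = (float)x[i];
  return X;
}

static NumericVector unpad_row(const fmat &P, const Dims &d) {
  NumericVector out((R_xlen_t)d.nx * d.ny * d.nz);
  R_xlen_t i = 0;
  for (int z = 0; z < d.nz; ++z)
    for (int y = 0; y < d.ny; ++y)
      for (int xx = 0; xx < d.nx; ++xx, ++i)
        out[i] = P(0, d.id(xx, y, z));
  return out;
}

// [[Rcpp::export]]
SEXP unet_create(int levels, int base, double slope, double drop, bool residual,
                 bool esum, bool skips, double dice_eps) {
  if (levels < 2) stop("levels must be >= 2");
  if (base < 1) stop("base_channels must be >= 1");
  if (drop < 0 || drop >= 1) stop("spatial_dropout_rate must be in [0, 1)");
  XPtr<UNet> p(new UNet(levels, base, slope, drop, residual, esum, skips, dice_eps), true);
  return p;
}

// [[Rcpp::export]]
double unet_num_params(SEXP ptr) {
  XPtr<UNet> net(ptr);
  double n = 0;
  for (const Conv &c : net->convs) n += (double)c.W.n_elem + c.b.n_elem;
  return n;
}

// [[Rcpp::export]]
List unet_get_config(SEXP ptr) {
  XPtr<UNet> net(ptr);
  return List::create(_["levels"] = net->levels, _["base_channels"] = net->base,
                      _["leaky_slope"] = net->slope,
                      _["spatial_dropout_rate"] = net->drop,
                      _["use_residual_blocks"] = net->residual,
                      _["use_elementwise_sum"] = net->esum,
                      _["use_skip_connections"] = net->skips,
                      _["dice_eps"] = net->dice_eps, _["adam_step"] = (double)net->step);
}

// [[Rcpp::export]]
NumericVector unet_forward(SEXP ptr, NumericVector x, IntegerVector dim, bool train) {
  XPtr<UNet> net(ptr);
  check_dims(*net, dim);
  const Dims d0 = {dim[0], dim[1], dim[2]};
  Cache K;
  forward(*net, pad_row(x, d0), d0, train, K);
  return unpad_row(K.p, d0);
}

// [[Rcpp::export]]
double unet_eval_loss(SEXP ptr, NumericVector x, NumericVector y, IntegerVector dim) {
  XPtr<UNet> net(ptr);
  check_dims(*net, dim);
  const Dims d0 = {dim[0], dim[1], dim[2]};
  Cache K;
  forward(*net, pad_row(x, d0), d0, false, K);
  return dice_loss(K.p, pad_row(y, d0), net->dice_eps, nullptr, d0);
}

// [[Rcpp::export]]
double unet_train_step(SEXP ptr, NumericVector x, NumericVector y, IntegerVector dim,
                       double lr, double beta1, double beta2, double eps) {
  XPtr<UNet> net(ptr);
  check_dims(*net, dim);
  const Dims d0 = {dim[0], dim[1], dim[2]};
  Cache K;
  forward(*net, pad_row(x, d0), d0, true, K);
  fmat dp;
  const double loss = dice_loss(K.p, pad_row(y, d0), net->dice_eps, &dp, d0);
  if (!std::isfinite(loss)) stop("non-finite training loss");
  zero_grads(*net);
  backward(*net, K, dp);
  adam_step(*net, lr, beta1, beta2, eps);
  return loss;
}

// Eval-mode loss + full gradient (no dropout, no update); for gradient checks.
// [[Rcpp::export]]
List unet_loss_grads(SEXP ptr, NumericVector x, NumericVector y, IntegerVector dim) {
  XPtr<UNet> net(ptr);
  check_dims(*net, dim);
  const Dims d0 = {dim[0], dim[1], dim[2]};
  Cache K;
  forward(*net, pad_row(x, d0), d0, false, K);
  fmat dp;
  const double loss = dice_loss(K.p, pad_row(y, d0), net->dice_eps, &dp, d0);
  zero_grads(*net);
  backward(*net, K, dp);
  List g;
  for (const Conv &c : net->convs) {
    g["W_" + c.name] = NumericMatrix(wrap(arma::conv_to<arma::mat>::from(c.gW)));
    g["b_" + c.name] = NumericVector(wrap(arma::conv_to<arma::vec>::from(c.gb)));
  }
  return List::create(_["loss"] = loss, _["grads"] = g);
}

// [[Rcpp::export]]
List unet_get_weights(SEXP ptr) {
  XPtr<UNet> net(ptr);
  List w;
  for (const Conv &c : net->convs) {
    w["W_" + c.name] = NumericMatrix(wrap(arma::conv_to<arma::mat>::from(c.W)));
    w["b_" + c.name] = NumericVector(wrap(arma::conv_to<arma::vec>::from(c.b)));
    w["mW_" + c.name] = NumericMatrix(wrap(arma::conv_to<arma::mat>::from(c.mW)));
    w["vW_" + c.name] = NumericMatrix(wrap(arma::conv_to<arma::mat>::from(c.vW)));
    w["mb_" + c.name] = NumericVector(wrap(arma::conv_to<arma::vec>::from(c.mb)));
    w["vb_" + c.name] = NumericVector(wrap(arma::conv_to<arma::vec>::from(c.vb)));
  }
  w["adam_step"] = (double)net->step;
  return w;
}

// [[Rcpp::export]]
void unet_set_weights(SEXP ptr, List w) {
  XPtr<UNet> net(ptr);
  for (Conv &c : net->convs) {
    c.W = arma::conv_to<fmat>::from(as<arma::mat>(w["W_" + c.name]));
    c.b = arma::conv_to<fvec>::from(as<arma::vec>(w["b_" + c.name]));
    if (w.containsElementNamed(("mW_" + c.name).c_str())) {
      c.mW = arma::conv_to<fmat>::from(as<arma::mat>(w["mW_" + c.name]));
      c.vW = arma::conv_to<fmat>::from(as<arma::mat>(w["vW_" + c.name]));
      c.mb = arma::conv_to<fvec>::from(as<arma::vec>(w["mb_" + c.name]));
      c.vb = arma::conv_to<fvec>::from(as<arma::vec>(w["vb_" + c.name]));
    }
  }
  if (w.containsElementNamed("adam_step")) net->step = (long)as<double>(w["adam_step"]);
}
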