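// Butcher tableau of the Dormand-Prince 8(5,3) explicit Runge-Kutta method
// (Hairer, Norsett & Wanner, Solving ODEs I, 2nd ed.). 12 stages, 8th-order
// solution with embedded 5th- and 3rd-order error estimators.
#ifndef DOP853_COEFFICIENTS_H
#define DOP853_COEFFICIENTS_H
static const int DOP_NSTAGES = 12;
static const double DOP_C[12] = {0.00000000000000000e+00, 5.26001519587677296e-02, 7.89002279381516014e-02, 1.18350341907227402e-01, 2.81649658092772592e-01, 3.33333333333333315e-01, 2.50000000000000000e-01, 3.07692307692307709e-01, 6.51282051282051300e-01, 5.99999999999999978e-01, 8.57142857142857095e-01, 1.00000000000000000e+00};
static const double DOP_B[12] = {5.42937341165687648e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 4.45031289275240916e+00, 1.89151789931450032e+00, -5.80120396001058491e+00, 3.11164366957819905e-01, -1.52160949662516087e-01, 2.01365400804030342e-01, 4.47106157277725874e-02};
static const double DOP_E3[13] = {-1.89800754072407624e-01, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 4.45031289275240916e+00, 1.89151789931450032e+00, -5.80120396001058491e+00, -4.22682321323791910e-01, -1.52160949662516087e-01, 2.01365400804030342e-01, 2.26517921983608213e-02, 0.00000000000000000e+00};
static const double DOP_E5[13] = {1.31200449941948800e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, -1.22515644637620436e+00, -4.95758949657250203e-01, 1.66437718245498645e+00, -3.50328848749973665e-01, 3.34179118713017476e-01, 8.19232064851157099e-02, -2.23553078638862937e-02, 0.00000000000000000e+00};
static const double DOP_A[12][12] = {
  {0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {5.26001519587677296e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {1.97250569845379004e-02, 5.91751709536137011e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {2.95875854768068505e-02, 0.00000000000000000e+00, 8.87627564304205446e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {2.41365134159266692e-01, 0.00000000000000000e+00, -8.84549479328286092e-01, 9.24834003261791993e-01, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {3.70370370370370350e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 1.70828608729473863e-01, 1.25467687566822417e-01, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {3.71093750000000000e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 1.70252211019544047e-01, 6.02165389804559595e-02, -1.75781250000000000e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {3.70920001185047893e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 1.70383925712239981e-01, 1.07262030446373280e-01, -1.53194377486244020e-02, 8.27378916381402325e-03, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {6.24110958716075692e-01, 0.00000000000000000e+00, 0.00000000000000000e+00, -3.36089262944694145e+00, -8.68219346841725970e-01, 2.75920996994467096e+01, 2.01540675504778939e+01, -4.34898841810699608e+01, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {4.77662536438264340e-01, 0.00000000000000000e+00, 0.00000000000000000e+00, -2.48811461997166772e+00, -5.90290826836842975e-01, 2.12300514481811931e+01, 1.52792336328824234e+01, -3.32882109689848633e+01, -2.03312017085086269e-02, 0.00000000000000000e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {-9.37142430085987299e-01, 0.00000000000000000e+00, 0.00000000000000000e+00, 5.18637242884406380e+00, 1.09143734899672951e+00, -8.14978701074692680e+00, -1.85200656599969591e+01, 2.27394870993505052e+01, 2.49360555267965234e+00, -3.04676447189821964e+00, 0.00000000000000000e+00, 0.00000000000000000e+00},
  {2.27331014751653804e+00, 0.00000000000000000e+00, 0.00000000000000000e+00, -1.05344954667372495e+01, -2.00087205822486247e+00, -1.79589318631187993e+01, 2.79488845294199599e+01, -2.85899827713502352e+00, -8.87285693353062932e+00, 1.23605671757943032e+01, 6.43392746015763572e-01, 0.00000000000000000e+00}
};
#endif
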