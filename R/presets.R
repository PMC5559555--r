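# Fitted genotype presets for the IKs Markov model.
#
# Transition-rate coefficients were obtained with fitParams() against the
# package's synthetic activation/kinetics fixtures (generateFixtures()
# defaults): the WT model fitted to a Boltzmann activation curve
# (V1/2 = +20 mV, k = 12 mV) with tail-deactivation and
# time-to-half-activation anchors matching slow delayed-rectifier
# kinetics at physiological temperature; the V307L model to the same
# curve shifted -36 mV with 2x slowed tail deactivation and 2x
# accelerated activation, started from the -36 mV voltage translation of
# the fitted WT model. The starting point of the WT fit was the classic
# cardiac IKs Markov parameterisation. gks is calibrated once so that
# the WT epicardial cell paced at 1 Hz gives APD90 = 325.6 ms; all other
# cellular and tissue outputs are predictions. The same values are
# mirrored in inst/extdata/iks_params_*.txt.

.iksSeedA <- c(alpha = 3.98e-4, beta = 5.74e-5, gamma = 3.41e-3,
               delta = 1.20e-3, theta = 6.47e-3, eta = 1.25e-2,
               psi = 6.33e-3, omega = 4.91e-3)
.iksSeedB <- c(alpha = 0.361, beta = -0.0923, gamma = 0.868,
               delta = -0.330, theta = 0, eta = -0.481,
               psi = 1.270, omega = -0.679) / 26.7137

.gksCalibrated <- 0.0824029541016

.iksPresets <- list(
  WT = list(
    a = c(alpha = 0.00050101357248268465,
          beta = 4.0198549008304425e-05,
          gamma = 0.010454780905609756,
          delta = 0.0012956699146503782,
          theta = 0.0036312677095578856,
          eta = 0.097850909163287855,
          psi = 0.076114674145708716,
          omega = 0.0044630545685363735),
    b = c(alpha = 0.01544948774997726,
          beta = -0.0079109615680484913,
          gamma = 0.04972323884749158,
          delta = -0.011393500852654663,
          theta = -0.03017069346758032,
          eta = 0.0013680056980103566,
          psi = 0.070270159762030313,
          omega = -0.022294013429157881),
    gks = .gksCalibrated,
    scale = 1),
  V307L = list(
    a = c(alpha = 0.00079134428395781487,
          beta = 0.00068011420489025483,
          gamma = 0.0087844492749366409,
          delta = 0.015999223080263966,
          theta = 1.3317039427936734,
          eta = 0.00050199251486460152,
          psi = 4.5080455217241786,
          omega = 3.0576711218799047e-06),
    b = c(alpha = 0.012984451982282612,
          beta = 0.051513903740213154,
          gamma = 0.049024417642057283,
          delta = 0.047948975738189278,
          theta = 0.10702194073761276,
          eta = -0.16244246472058818,
          psi = 0.028630045007697412,
          omega = -0.25897693622491924),
    gks = .gksCalibrated,
    # saturation-normalising relative amplitude (saturationScale()):
    # equal channel expression, amplitude differences from gating only
    scale = 2.0478738901156861)
)
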