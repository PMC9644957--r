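test_that("mechanical advantage is the in/out lever ratio", {
  expect_equal(mechanical_advantage(10, 10), 1)
  expect_equal(mechanical_advantage(10, 100), 0.1)
  expect_error(mechanical_advantage(-1, 10), "positive")
  expect_error(mechanical_advantage(10, 0), "positive")
  expect_warning(mechanical_advantage(20, 10), "implausible")
})

test_that("lever bite forces reproduce the reference worked examples", {
  dims <- muscle_dimensions()
  f_rob <- total_muscle_force(specimen_muscles("M1409", dims))
  f_gra <- total_muscle_force(specimen_muscles("M1399", dims))
  lv <- lever_fixtures()
  a_rob <- lv$mechanical_advantage_tip[lv$specimen == "M1409"]
  a_gra <- lv$mechanical_advantage_tip[lv$specimen == "M1399"]
  expect_equal(a_rob, 0.089)
  expect_equal(a_gra, 0.191)
  expect_equal(round_half_out(bite_force(f_rob, a_rob)), 14)
  expect_equal(round_half_out(bite_force(f_gra, a_gra)), 56)
  expect_equal(bite_force(f_gra, 1), f_gra) # A = 1 identity
  expect_equal(bite_force(0, 0.5), 0)
  expect_error(bite_force(-1, 0.5), ">= 0")
  expect_warning(bite_force(10, 1.2), "implausible")
})

test_that("bite profile is monotone and inversely proportional to the out-lever", {
  lever <- lever_geometry(in_lever = 0.191 * 335, out_lever_tip = 335,
                          out_lever_back = 120)
  bp <- bite_profile(lever, 291.12,
                     positions = c(tip = 335, mid = 228, back = 120))
  expect_true(all(diff(bp$force_N) > 0)) # increases towards the joint
  expect_equal(bp$force_N[bp$position == "tip"],
               bite_force(291.12, lever$mechanical_advantage_A))
  # halving the out-lever at fixed in-lever doubles the force
  bp2 <- bite_profile(lever, 291.12, positions = c(a = 200, b = 100))
  expect_equal(bp2$force_N[2], 2 * bp2$force_N[1])
  expect_error(bite_profile(lever, 291.12, positions = c(far = 400)),
               "out_lever_tip")
})

test_that("back-of-tooth-row forces back-solve to the reference values", {
  dims <- muscle_dimensions()
  f_rob <- total_muscle_force(specimen_muscles("M1409", dims))
  f_gra <- total_muscle_force(specimen_muscles("M1399", dims))
  # implied mechanical advantages at the back of the tooth row
  a_back_rob <- 68 / f_rob
  a_back_gra <- 181 / f_gra
  expect_equal(round(a_back_rob, 3), 0.430)
  expect_equal(round(a_back_gra, 3), 0.622)
  # implied out-levers reproduce the printed back-of-row forces
  in_rob <- 0.089 * 401
  in_gra <- 0.191 * 335
  out_rob <- implied_out_lever(f_rob, in_rob, 68)
  out_gra <- implied_out_lever(f_gra, in_gra, 181)
  bp_rob <- bite_profile(lever_geometry(in_rob, 401, out_rob), f_rob,
                         positions = c(back = out_rob))
  bp_gra <- bite_profile(lever_geometry(in_gra, 335, out_gra), f_gra,
                         positions = c(back = out_gra))
  expect_equal(bp_rob$force_rounded, 68)
  expect_equal(bp_gra$force_rounded, 181)
})

test_that("lever geometry invariants are enforced", {
  expect_error(lever_geometry(100, 90), "in_lever < out_lever_back")
  expect_error(lever_geometry(-5, 90), "positive")
  lg <- lever_geometry(30, 300)
  expect_equal(lg$mechanical_advantage_A, 0.1)
})
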