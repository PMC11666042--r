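# Internal functions exercised directly by the white-box tests.
mlp_eval        <- odepinn:::mlp_eval
mlp_backward    <- odepinn:::mlp_backward
net_flatten     <- odepinn:::net_flatten
net_unflatten   <- odepinn:::net_unflatten
net_nparams     <- odepinn:::net_nparams
adam_init       <- odepinn:::adam_init
adam_step       <- odepinn:::adam_step
pinn_model      <- odepinn:::pinn_model
model_flatten   <- odepinn:::model_flatten
model_unflatten <- odepinn:::model_unflatten
model_grad_flat <- odepinn:::model_grad_flat
data_pass       <- odepinn:::data_pass
ode_pass        <- odepinn:::ode_pass
total_loss      <- odepinn:::total_loss
loss_components <- odepinn:::loss_components
residual_factor <- odepinn:::residual_factor
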